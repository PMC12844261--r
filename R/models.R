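#' Construct a fixed-coefficient linear QSAR model
#'
#' A `qsar_model` is an intercept plus a set of named descriptor
#' coefficients, optionally with standard errors, predicting a log10
#' property (`logKoc`, `logBCF` or `logKpuu`).  The four published models
#' shipped with the package ([model_koc()], [model_bcf()], [model_kpuu()],
#' [model_kpuu_lit()]) are instances of this class; [qsar_stepwise()] returns
#' a subclass fitted from data.
#'
#' @param property One of `"logKoc"`, `"logBCF"`, `"logKpuu"`.
#' @param intercept Numeric intercept (log10 units of the property).
#' @param coefficients Named numeric vector of term coefficients; names must
#'   be recognized descriptors.
#' @param se Optional named numeric vector of term standard errors.
#' @param intercept_se Optional numeric standard error of the intercept.
#' @param provenance Free-text citation or description of origin.
#' @return An object of class `qsar_model`.
#' @examples
#' m <- qsar_model("logKoc", 1, c(logP = 0.5), provenance = "toy")
#' predict(m, data.frame(logP = 2))
#' @export
qsar_model <- function(property, intercept, coefficients, se = NULL,
                       intercept_se = NULL, provenance = "") {
  property <- match.arg(property, c("logKoc", "logBCF", "logKpuu"))
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  unknown <- setdiff(names(coefficients), descriptor_registry()$name)
  if (length(unknown))
    stop("unrecognized descriptor term(s): ", paste(unknown, collapse = ", "))
  if (!is.null(se)) stopifnot(identical(names(se), names(coefficients)))
  structure(list(property = property,
                 intercept = unname(intercept),
                 coefficients = coefficients,
                 se = se,
                 intercept_se = intercept_se,
                 provenance = provenance),
            class = "qsar_model")
}

#' Published MLR model of soil sorption (log Koc)
#'
#' Fixed-coefficient multiple linear regression predicting the soil-water
#' partition coefficient normalized to organic carbon from rotatable-bond
#' count, heteroatom count, ring count, PAMPA high-permeability probability,
#' aqueous solubility (log S) and lipophilicity (log P).  Trained on 632
#' reference compounds (500 train / 132 test).
#'
#' @return A `qsar_model` for `logKoc`.
#' @export
model_koc <- function() {
  qsar_model(
    "logKoc",
    intercept    = 0.921, intercept_se = 0.067,
    coefficients = c(nRot = -0.0441, nHet = 0.0309, nRing = 0.152,
                     PAMPA = -0.272, logS = -0.201, logP = 0.356),
    se           = c(nRot = 0.0091, nHet = 0.0109, nRing = 0.029,
                     PAMPA = 0.074, logS = 0.033, logP = 0.034),
    provenance   = "published stepwise MLR, log Koc reference set (n = 632)")
}

#' Published MLR model of fish bioconcentration (log BCF)
#'
#' Predicts the fish bioconcentration factor from rotatable-bond count,
#' largest-ring size, PAMPA high-permeability probability, aqueous
#' solubility (log S) and the pH 7.4 distribution coefficient (log D).
#' Trained on 556 reference compounds (400 train / 156 test).
#'
#' @return A `qsar_model` for `logBCF`.
#' @export
model_bcf <- function() {
  qsar_model(
    "logBCF",
    intercept    = 0.668, intercept_se = 0.133,
    coefficients = c(nRot = -0.130, MaxRing = -0.0901, PAMPA = -0.543,
                     logS = -0.251, logD = 0.493),
    se           = c(nRot = 0.011, MaxRing = 0.0138, PAMPA = 0.128,
                     logS = 0.040, logD = 0.075),
    provenance   = "published stepwise MLR, log BCF reference set (n = 556)")
}

#' Published MLR model of unbound brain-to-plasma ratio (log Kp,uu)
#'
#' Predicts the unbound brain-to-plasma partition coefficient from
#' topological polar surface area, heteroatom count, the fraction of sp3
#' carbons and MDCK permeability.  Trained on 74 reference compounds
#' (60 train / 14 test, rat in vivo data).
#'
#' @return A `qsar_model` for `logKpuu`.
#' @export
model_kpuu <- function() {
  qsar_model(
    "logKpuu",
    intercept    = 6.81, intercept_se = 1.37,
    coefficients = c(TPSA = -0.0118, nHet = -0.0971, Fsp3 = 0.670,
                     MDCK = 1.31),
    se           = c(TPSA = 0.0034, nHet = 0.0373, Fsp3 = 0.329,
                     MDCK = 0.30),
    provenance   = "published stepwise MLR, log Kp,uu reference set (n = 74)")
}

#' Literature comparison model of log Kp,uu
#'
#' An earlier published equation predicting log Kp,uu from heavy-atom count,
#' H-bond donor count, molar refractivity and iLOGP; used as an external
#' comparator for the in-house log Kp,uu models.  No standard errors were
#' reported.
#'
#' @return A `qsar_model` for `logKpuu`.
#' @export
model_kpuu_lit <- function() {
  qsar_model(
    "logKpuu",
    intercept    = 0.866,
    coefficients = c(HeavyAtoms = -0.211, HBD = -0.250, MR = 0.0272,
                     iLOGP = 0.483),
    provenance   = "literature log Kp,uu equation (external comparator)")
}

#' Predict a log property from descriptors
#'
#' Evaluates `intercept + sum(coefficient * descriptor)` for each row of
#' `newdata`.  Pure and deterministic; a missing descriptor column or value
#' is an error naming the descriptor (values are never imputed).
#'
#' @param object A `qsar_model`.
#' @param newdata Data frame (or single named numeric vector) of
#'   descriptors; must contain every term of the model.
#' @param ... Unused.
#' @return Numeric vector of predicted log10 property values, named by
#'   compound `id` when `newdata` has an `id` column.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  stopifnot(is.data.frame(newdata))
  vars <- names(object$coefficients)
  X <- descriptor_matrix(newdata, vars)
  out <- drop(object$intercept + X %*% object$coefficients[vars])
  if ("id" %in% names(newdata)) names(out) <- newdata$id
  out
}

#' @export
coef.qsar_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.qsar_model <- function(x, digits = 4, ...) {
  cat("Linear QSAR model of", x$property, "\n")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  cf <- coef(x)
  se <- c(x$intercept_se %||% NA_real_,
          if (is.null(x$se)) rep(NA_real_, length(x$coefficients)) else x$se)
  tab <- data.frame(coefficient = signif(cf, digits),
                    se = signif(se, digits), row.names = names(cf))
  print(tab)
  invisible(x)
}

#' Simulate responses from a QSAR model
#'
#' Draws `nsim` replicate response vectors `predict(object, newdata) +
#' Normal(0, noise_sd)`; this is the generating process the synthetic
#' reference datasets use.
#'
#' @param object A `qsar_model`.
#' @param nsim Number of replicate response vectors.
#' @param seed Integer seed (required; the global RNG state is untouched).
#' @param newdata Descriptor data frame.
#' @param noise_sd Gaussian noise standard deviation, log10 units.
#' @param ... Unused.
#' @return Data frame with `nsim` columns `sim_1 ... sim_nsim`.
#' @export
simulate.qsar_model <- function(object, nsim = 1, seed = 1, newdata,
                                noise_sd = 0.4, ...) {
  mu <- predict(object, newdata)
  with_seed(seed, {
    out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, noise_sd))
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize / parse a QSAR model as JSON
#'
#' Coefficients are written as full-precision decimal strings so that
#' serialize-then-parse reproduces every coefficient bit-exactly.
#'
#' @param model A `qsar_model`.
#' @param path Optional path; if given the JSON is written there.
#' @return `model_to_json`: JSON string (invisibly if `path` given);
#'   `model_from_json`: the reconstructed `qsar_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "qsar_model"))
  num <- function(v) if (is.null(v)) NULL else sprintf("%.17g", v)
  obj <- list(property = model$property,
              intercept = num(model$intercept),
              terms = as.list(stats::setNames(num(model$coefficients),
                                              names(model$coefficients))),
              term_se = if (is.null(model$se)) NULL else
                as.list(stats::setNames(num(model$se), names(model$se))),
              intercept_se = num(model$intercept_se),
              provenance = model$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  num <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  named <- function(v) if (is.null(v)) NULL else
    stats::setNames(as.numeric(unlist(v)), names(v))
  qsar_model(obj$property, num(obj$intercept), named(obj$terms),
             se = named(obj$term_se), intercept_se = num(obj$intercept_se),
             provenance = obj$provenance %||% "")
}

#' Apparent permeability from a cell-monolayer assay
#'
#' `Papp = (dQ/dt) / (C0 * A)`: permeation rate across the monolayer divided
#' by donor concentration at time zero and monolayer area.  Units follow the
#' inputs, (amount/time) / (concentration x area); with dQ/dt in mol/s, C0 in
#' mol/cm^3 and A in cm^2 the result is cm/s.
#'
#' @param dQdt Permeation rate (amount/time).
#' @param C0 Donor concentration at time zero (> 0).
#' @param A Monolayer area (> 0).
#' @return Apparent permeability, same sign as `dQdt`.
#' @export
apparent_permeability <- function(dQdt, C0, A) {
  if (any(C0 <= 0)) stop("donor concentration C0 must be positive")
  if (any(A <= 0)) stop("monolayer area A must be positive")
  dQdt / (C0 * A)
}

#' Effective permeability from a PAMPA assay
#'
#' With donor volume `VD`, acceptor volume `VA`, membrane area and
#' incubation time, the cell constant is
#' `C = (VD * VA) / ((VD + VA) * Area * Time)` and the effective
#' permeability is `Pe = -C * ln(1 - fA)` where `fA` is the ratio of the
#' acceptor-compartment concentration to the equilibrium concentration.
#' The leading minus makes `Pe` non-negative, the convention under which
#' PAMPA permeabilities are reported.
#'
#' @param VD,VA Donor and acceptor compartment volumes (> 0).
#' @param area Membrane area (> 0).
#' @param time Incubation time (> 0).
#' @param acceptor_fraction `[drug]_acceptor / [drug]_equilibrium`, in
#'   `[0, 1)`; 1 or more means equilibrium was reached or exceeded and is an
#'   error.
#' @return Effective permeability `Pe >= 0`; strictly increasing in
#'   `acceptor_fraction` and divergent as it approaches 1.
#' @export
effective_permeability <- function(VD, VA, area, time, acceptor_fraction) {
  if (any(c(VD, VA, area, time) <= 0))
    stop("volumes, area and time must all be positive")
  if (any(acceptor_fraction < 0)) stop("acceptor_fraction must be >= 0")
  if (any(acceptor_fraction >= 1))
    stop("acceptor_fraction must be < 1 (equilibrium exceeded)")
  C <- (VD * VA) / ((VD + VA) * area * time)
  -C * log(1 - acceptor_fraction)
}
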