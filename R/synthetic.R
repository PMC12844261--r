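#' Configuration for a synthetic reference dataset
#'
#' Describes the generating process used to emulate the reference datasets
#' behind the published models: descriptor vectors drawn independently
#' within per-descriptor ranges (counts as integer uniforms, unit-interval
#' descriptors as uniforms on \[0, 1\]), a response generated from a linear
#' QSAR model plus Gaussian noise, and a random train/test(/validation)
#' split of configured sizes.
#'
#' Defaults reproduce the published study conditions per property: split
#' sizes 500/132 (log Koc), 400/156 (log BCF), 60/14 (log Kp,uu); noise
#' standard deviation 0.4 log units (0.3 for log Kp,uu, whose reference
#' measurements span a narrower range); descriptor ranges including the
#' reference log P span of -2.2 to +9.9.
#'
#' @param property One of `"logKoc"`, `"logBCF"`, `"logKpuu"`.
#' @param generating_model A `qsar_model` supplying the noiseless response
#'   (default: the built-in published model for `property`).
#' @param n_train,n_test,n_validation Split sizes (defaults per property;
#'   `n_validation` defaults to 0).
#' @param noise_sd Gaussian noise standard deviation, log10 units.
#' @param seed Integer seed.
#' @param ranges Named list of `c(low, high)` descriptor ranges; merged
#'   over the per-property defaults.
#' @param collinear_spec Optional list of `list(pair = c(a, b), r = target)`
#'   entries injecting a known correlation between two descriptors via a
#'   Gaussian copula (marginals stay uniform within their ranges);
#'   `|r| >= 1` is infeasible and an error.
#' @param family_spec Optional family specification as in
#'   [gen_drug_panel()], attaching family tags and descriptor offsets.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(property,
                             generating_model = NULL,
                             n_train = NULL, n_test = NULL,
                             n_validation = 0,
                             noise_sd = NULL, seed = 1,
                             ranges = NULL, collinear_spec = NULL,
                             family_spec = NULL) {
  property <- match.arg(property, c("logKoc", "logBCF", "logKpuu"))
  defaults <- switch(property,
    logKoc = list(model = model_koc, n_train = 500, n_test = 132,
                  noise = 0.4,
                  ranges = list(nRot = c(0, 20), nHet = c(0, 15),
                                nRing = c(0, 6), PAMPA = c(0, 1),
                                logS = c(-10, 1), logP = c(-2.2, 9.9))),
    logBCF = list(model = model_bcf, n_train = 400, n_test = 156,
                  noise = 0.4,
                  ranges = list(nRot = c(0, 20), MaxRing = c(0, 18),
                                PAMPA = c(0, 1), logS = c(-10, 1),
                                logD = c(-4, 8))),
    logKpuu = list(model = model_kpuu, n_train = 60, n_test = 14,
                   noise = 0.3,
                   ranges = list(TPSA = c(0, 250), nHet = c(0, 20),
                                 Fsp3 = c(0, 1), MDCK = c(-6, -4),
                                 logVDss = c(-1, 1.5))))
  generating_model <- generating_model %||% defaults$model()
  stopifnot(inherits(generating_model, "qsar_model"))
  n_train <- n_train %||% defaults$n_train
  n_test <- n_test %||% defaults$n_test
  noise_sd <- noise_sd %||% defaults$noise
  stopifnot(n_train >= 0, n_test >= 0, n_validation >= 0, noise_sd >= 0)
  all_ranges <- defaults$ranges
  for (nm in names(ranges)) all_ranges[[nm]] <- ranges[[nm]]
  for (nm in names(all_ranges)) {
    r <- all_ranges[[nm]]
    if (length(r) != 2 || !(r[1] < r[2]))
      stop("range for ", nm, " must be c(low, high) with low < high")
  }
  missing_terms <- setdiff(names(generating_model$coefficients),
                           names(all_ranges))
  if (length(missing_terms))
    stop("no range configured for generating-model term(s): ",
         paste(missing_terms, collapse = ", "))
  if (!is.null(collinear_spec)) {
    for (cs in collinear_spec) {
      stopifnot(length(cs$pair) == 2, all(cs$pair %in% names(all_ranges)))
      if (abs(cs$r) >= 1)
        stop("infeasible collinear_spec: |r| must be < 1")
    }
  }
  structure(list(property = property, generating_model = generating_model,
                 n_train = n_train, n_test = n_test,
                 n_validation = n_validation, noise_sd = noise_sd,
                 seed = seed, ranges = all_ranges,
                 collinear_spec = collinear_spec,
                 family_spec = family_spec),
            class = "synthetic_config")
}

is_count_descriptor <- function(name) {
  reg <- descriptor_registry()
  t <- reg$type[match(name, reg$name)]
  !is.na(t) & t == "count"
}

draw_descriptor <- function(name, n, range) {
  if (is_count_descriptor(name)) {
    sample(seq(range[1], range[2]), n, replace = TRUE)
  } else {
    stats::runif(n, range[1], range[2])
  }
}

# Map a standard-normal draw onto a descriptor's range, preserving the
# uniform marginal (Gaussian copula); counts are discretized afterwards.
copula_map <- function(z, name, range) {
  u <- stats::pnorm(z)
  v <- range[1] + u * (range[2] - range[1])
  if (is_count_descriptor(name)) round(v) else v
}

#' Generate a synthetic reference dataset
#'
#' Draws descriptors per the configuration, computes the response as the
#' generating model's prediction plus Gaussian noise, and assigns a random
#' split of the configured sizes.  Fully reproducible under the
#' configuration seed, and never touches the global RNG state.
#'
#' @param cfg A [synthetic_config()].
#' @return A [qsar_data] object; compound ids are `cmpd0001 ...`.
#' @examples
#' d <- gen_reference_dataset(synthetic_config("logKoc", n_train = 30,
#'                                             n_test = 10, seed = 2))
#' d
#' @export
gen_reference_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_train + cfg$n_test + cfg$n_validation
  if (n < 1) stop("configuration generates no compounds")
  with_seed(cfg$seed, {
    cols <- lapply(names(cfg$ranges), function(nm)
      draw_descriptor(nm, n, cfg$ranges[[nm]]))
    names(cols) <- names(cfg$ranges)
    if (!is.null(cfg$collinear_spec)) {
      for (cs in cfg$collinear_spec) {
        z1 <- stats::rnorm(n)
        z2 <- cs$r * z1 + sqrt(1 - cs$r^2) * stats::rnorm(n)
        a <- cs$pair[1]; b <- cs$pair[2]
        cols[[a]] <- copula_map(z1, a, cfg$ranges[[a]])
        cols[[b]] <- copula_map(z2, b, cfg$ranges[[b]])
      }
    }
    compounds <- data.frame(id = sprintf("cmpd%04d", seq_len(n)), cols,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(cfg$family_spec))
      compounds <- apply_family_spec(compounds, cfg$family_spec)
    mu <- predict(cfg$generating_model, compounds)
    response <- mu + stats::rnorm(n, 0, cfg$noise_sd)
    split <- sample(rep(c("train", "test", "validation"),
                        c(cfg$n_train, cfg$n_test, cfg$n_validation)))
    qsar_data(compounds, response, split, cfg$property)
  })
}

#' Generate a correlated descriptor pair
#'
#' A bivariate-normal pair with target correlation `r_target`, the fixture
#' used to exercise the collinearity screen; the sample correlation lands
#' within about ±0.03 of the target for n >= 500.
#'
#' @param n Number of rows (>= 10).
#' @param r_target Target correlation, `|r_target| < 1`.
#' @param seed Integer seed.
#' @return Data frame with columns `x1`, `x2` (standard-normal marginals).
#' @export
gen_collinear_block <- function(n, r_target, seed = 1) {
  if (n < 10) stop("need n >= 10")
  if (abs(r_target) >= 1) stop("|r_target| must be < 1")
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- r_target * z1 + sqrt(1 - r_target^2) * stats::rnorm(n)
    data.frame(x1 = z1, x2 = z2)
  })
}

# Default family composition of the synthetic drug panel: fractions and
# lipophilicity/solubility offsets that make salicylanilide- and
# pyrethroid-like compounds less mobile and more bioconcentrating than
# sulfonamide-like ones.
default_family_spec <- function() {
  list(
    benzimidazole   = list(fraction = 0.25, offsets = c()),
    organophosphate = list(fraction = 0.20, offsets = c()),
    pyrethroid      = list(fraction = 0.15,
                           offsets = c(logP = 2, logS = -1.5, logD = 1.5)),
    salicylanilide  = list(fraction = 0.10,
                           offsets = c(logP = 2.5, logS = -2, logD = 2)),
    sulfonamide     = list(fraction = 0.15,
                           offsets = c(logP = -1.5, logS = 1.5, logD = -1.5)),
    other           = list(fraction = 0.15, offsets = c())
  )
}

apply_family_spec <- function(compounds, family_spec) {
  fracs <- vapply(family_spec, `[[`, numeric(1), "fraction")
  if (abs(sum(fracs) - 1) > 1e-8) stop("family fractions must sum to 1")
  n <- nrow(compounds)
  counts <- floor(fracs * n)
  counts[counts == 0] <- 1L
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n) {
    rem <- fracs * n - counts
    counts[which.max(rem)] <- counts[which.max(rem)] + 1L
  }
  fam <- rep(names(family_spec), counts)
  compounds$family <- fam
  for (f in names(family_spec)) {
    off <- family_spec[[f]]$offsets
    for (d in names(off)) {
      if (d %in% names(compounds))
        compounds[[d]][fam == f] <- compounds[[d]][fam == f] + off[[d]]
    }
  }
  compounds
}

#' Generate a synthetic antiparasitic drug panel
#'
#' Emulates a panel of veterinary antiparasitic drugs across the main
#' chemical families (benzimidazoles, organophosphates, pyrethroids,
#' salicylanilides, sulfonamides, other), with family-specific descriptor
#' offsets — salicylanilide- and pyrethroid-like compounds drawn with
#' higher log P / lower log S — so that per-family summaries and
#' classifications are exercised with a realistic ordering.  The panel
#' carries every descriptor needed by the four built-in models and by all
#' threshold classifiers.  These are synthetic compounds: the descriptor
#' combinations need not be realizable by an actual molecule.
#'
#' @param n Panel size (default 86).
#' @param family_spec Named list, one entry per family, each
#'   `list(fraction =, offsets = c(descriptor = shift, ...))`; fractions
#'   must sum to 1.  Defaults to the built-in composition.
#' @param seed Integer seed.
#' @return Data frame of compound records (`id`, `name`, `family`,
#'   `smiles`, descriptors); at least one compound per family.
#' @export
gen_drug_panel <- function(n = 86, family_spec = NULL, seed = 1) {
  family_spec <- family_spec %||% default_family_spec()
  base_ranges <- list(
    nRot = c(0, 15), nHet = c(2, 15), nRing = c(0, 5), MaxRing = c(5, 16),
    PAMPA = c(0, 1), logS = c(-7, 0), logP = c(-1, 7), logD = c(-2, 6),
    TPSA = c(20, 200), Fsp3 = c(0, 1), MDCK = c(-6, -4),
    caco2 = c(-6.2, -4), HIA = c(20, 100), MW = c(150, 700),
    MLOGP = c(-2, 6), nHA = c(0, 12), nHD = c(0, 6),
    HeavyAtoms = c(10, 50), MR = c(20, 150), iLOGP = c(-1, 5),
    logVDss = c(-1, 1.5))
  with_seed(seed, {
    cols <- lapply(names(base_ranges), function(nm)
      draw_descriptor(nm, n, base_ranges[[nm]]))
    names(cols) <- names(base_ranges)
    cols$HBD <- cols$nHD    # both name the H-bond donor count
    panel <- data.frame(id = sprintf("drug%03d", seq_len(n)),
                        name = sprintf("synthetic-antiparasitic-%03d",
                                       seq_len(n)),
                        smiles = NA_character_, cols,
                        stringsAsFactors = FALSE, check.names = FALSE)
    panel <- apply_family_spec(panel, family_spec)
    panel[, c("id", "name", "family", "smiles",
              setdiff(names(panel),
                      c("id", "name", "family", "smiles")))]
  })
}
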