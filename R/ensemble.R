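#' Boosted-tree regression model of a log property
#'
#' Gradient-boosted regression trees with squared-error loss (via xgboost,
#' single-threaded for reproducibility), fit on the training split and
#' validated by training R^2 and external RMSE of prediction.  Descriptor
#' importances are gain-based, rescaled so the most important descriptor
#' scores exactly 1 (relative-importance convention).
#'
#' @param data A [qsar_data] object.
#' @param candidates Character vector of descriptor names to use.
#' @param n_trees Number of boosting rounds (default 200).
#' @param depth Maximum tree depth (default 3).
#' @param learning_rate Shrinkage per round (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `qsar_bt`: `booster`, `candidates`, `importance`
#'   (data frame `descriptor`/`importance`, max exactly 1, sorted
#'   descending), `R2_train`, `RMSE_pred` (`NA` without a test split) and
#'   the parameters.
#' @examples
#' cfg <- synthetic_config("logKoc", n_train = 80, n_test = 20, seed = 3)
#' d <- gen_reference_dataset(cfg)
#' bt <- qsar_bt(d, names(model_koc()$coefficients), n_trees = 50, seed = 3)
#' bt$importance
#' @export
qsar_bt <- function(data, candidates, n_trees = 200, depth = 3,
                    learning_rate = 0.05, seed = 1) {
  stopifnot(inherits(data, "qsar_data"), length(candidates) >= 1,
            n_trees >= 1, depth >= 1, learning_rate > 0, learning_rate <= 1)
  tr <- split_rows(data, "train")
  X <- descriptor_matrix(tr$compounds, candidates)
  y <- tr$response
  if (stats::sd(y) == 0) stop("degenerate (constant) response")
  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = as.integer(depth),
                    eta = learning_rate, nthread = 1,
                    seed = as.integer(seed)),
      data = dtrain, nrounds = as.integer(n_trees), verbose = 0)
  })
  imp_raw <- xgboost::xgb.importance(model = booster)
  gain <- stats::setNames(rep(0, length(candidates)), candidates)
  if (!is.null(imp_raw) && nrow(imp_raw))
    gain[imp_raw$Feature] <- imp_raw$Gain
  if (max(gain) > 0) gain <- gain / max(gain)
  importance <- data.frame(descriptor = names(gain),
                           importance = unname(gain),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  rownames(importance) <- NULL

  obj <- structure(list(booster = booster, candidates = candidates,
                        importance = importance,
                        params = list(n_trees = n_trees, depth = depth,
                                      learning_rate = learning_rate,
                                      seed = seed),
                        R2_train = NA_real_, RMSE_pred = NA_real_),
                   class = "qsar_bt")
  pred_tr <- predict(obj, tr$compounds)
  obj$R2_train <- 1 - sum((y - pred_tr)^2) / sum((y - mean(y))^2)
  if (any(data$split == "test")) obj$RMSE_pred <- rmse_pred(obj, data)
  obj
}

#' @export
predict.qsar_bt <- function(object, newdata, ...) {
  X <- descriptor_matrix(newdata, object$candidates)
  out <- predict(object$booster, xgboost::xgb.DMatrix(X))
  if ("id" %in% names(newdata)) names(out) <- newdata$id
  out
}

#' @export
print.qsar_bt <- function(x, ...) {
  cat("Boosted-tree QSAR model:", x$params$n_trees, "trees, depth",
      x$params$depth, ", learning rate", x$params$learning_rate, "\n")
  cat(sprintf("  R2_train = %.4f  RMSE_pred = %s\n", x$R2_train,
              if (is.na(x$RMSE_pred)) "NA" else sprintf("%.4f", x$RMSE_pred)))
  cat("Relative importances (max = 1):\n")
  print(x$importance, row.names = FALSE, digits = 3)
  invisible(x)
}

# --- single-hidden-layer perceptrons -------------------------------------
# Activation functions and their derivatives in terms of the pre-activation.
# "exponential" is clamped at 30 to keep the BFGS objective finite.
act_fun <- function(name) {
  switch(name,
    identity    = list(f = function(z) z,
                       df = function(z) rep(1, length(z))),
    logistic    = list(f = function(z) 1 / (1 + exp(-z)),
                       df = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
    tanh        = list(f = function(z) tanh(z),
                       df = function(z) 1 - tanh(z)^2),
    exponential = list(f = function(z) exp(pmin(z, 30)),
                       df = function(z) exp(pmin(z, 30))),
    stop("unknown activation: ", name))
}

mlp_unpack <- function(w, p, H) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(p * H)], p, H); i <- i + p * H
  b1 <- w[i + seq_len(H)]; i <- i + H
  w2 <- w[i + seq_len(H)]; i <- i + H
  b2 <- w[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(w, X, hid, out) {
  p <- ncol(X); H <- (length(w) - 1L) / (p + 2L)
  par <- mlp_unpack(w, p, H)
  Z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  A1 <- hid$f(Z1)
  z2 <- drop(A1 %*% par$w2) + par$b2
  list(yhat = out$f(z2), Z1 = Z1, A1 = A1, z2 = z2, par = par)
}

mlp_sse <- function(w, X, y, hid, out) {
  fw <- mlp_forward(w, X, hid, out)
  v <- sum((fw$yhat - y)^2)
  if (!is.finite(v)) 1e12 else v
}

mlp_grad <- function(w, X, y, hid, out) {
  fw <- mlp_forward(w, X, hid, out)
  r <- fw$yhat - y
  if (!all(is.finite(r))) return(rep(0, length(w)))
  dz2 <- 2 * r * out$df(fw$z2)
  gw2 <- drop(crossprod(fw$A1, dz2))
  gb2 <- sum(dz2)
  dZ1 <- (dz2 %o% fw$par$w2) * hid$df(fw$Z1)
  gW1 <- crossprod(X, dZ1)
  gb1 <- colSums(dZ1)
  g <- c(as.vector(gW1), gb1, gw2, gb2)
  g[!is.finite(g)] <- 0
  g
}

#' Ensemble of single-hidden-layer neural networks
#'
#' A reduced automated network search: `n_nets` multilayer perceptrons with
#' one hidden layer are trained on the (standardized) training split with a
#' quasi-Newton optimizer (BFGS) minimizing the sum-of-squares error.  Each
#' candidate network draws its hidden-layer size from `hidden_range` and its
#' hidden/output activation pair from `activations` (identity, logistic,
#' hyperbolic tangent, exponential).  The `n_retain` networks with the
#' highest validation-split correlation are retained; model quality is
#' reported as Pearson correlation per split.  Networks that fail to train
#' are discarded, never fatal.
#'
#' When the dataset has no `"validation"` split, 15% of the training rows
#' (at least one) are carved off deterministically under `seed` to serve as
#' the validation subset.
#'
#' @param data A [qsar_data] object.
#' @param candidates Character vector of input descriptor names.
#' @param n_nets Number of networks to train (default 50).
#' @param n_retain Number of networks to retain (default 5).
#' @param hidden_range Integer vector of admissible hidden-layer sizes.
#' @param activations Activation names to sample from.
#' @param seed Integer seed governing architecture sampling, weight
#'   initialization and the validation carve-out.
#' @param maxit BFGS iteration cap per network.
#' @return Object of class `qsar_ann`: `nets` (list of retained networks,
#'   best validation correlation first, each with `hidden`, `hidden_act`,
#'   `output_act`, weights and per-split correlations), `correlations`
#'   (data frame net x split), `candidates`, scaling info.
#' @export
qsar_ann <- function(data, candidates, n_nets = 50, n_retain = 5,
                     hidden_range = 2:8,
                     activations = c("identity", "logistic", "tanh",
                                     "exponential"),
                     seed = 1, maxit = 300) {
  stopifnot(inherits(data, "qsar_data"), length(candidates) >= 1,
            n_nets >= 1, n_retain >= 1, n_retain <= n_nets)
  activations <- match.arg(activations, several.ok = TRUE)

  tr_idx <- which(data$split == "train")
  va_idx <- which(data$split == "validation")
  te_idx <- which(data$split == "test")
  carve <- length(va_idx) == 0L
  if (carve) {
    n_va <- max(1L, round(0.15 * length(tr_idx)))
    va_idx <- with_seed(seed, sample(tr_idx, n_va))
    tr_idx <- setdiff(tr_idx, va_idx)
  }
  Xall <- descriptor_matrix(data$compounds, candidates)
  y <- data$response
  mu_x <- colMeans(Xall[tr_idx, , drop = FALSE])
  sd_x <- apply(Xall[tr_idx, , drop = FALSE], 2, stats::sd)
  if (any(sd_x == 0)) stop("zero-variance candidate(s): ",
                           paste(candidates[sd_x == 0], collapse = ", "))
  mu_y <- mean(y[tr_idx]); sd_y <- stats::sd(y[tr_idx])
  if (sd_y == 0) stop("degenerate (constant) response")
  Z <- sweep(sweep(Xall, 2, mu_x), 2, sd_x, "/")
  ys <- (y - mu_y) / sd_y

  nets <- with_seed(seed, {
    lapply(seq_len(n_nets), function(k) {
      H <- if (length(hidden_range) == 1L) hidden_range else
        sample(hidden_range, 1L)
      hid_name <- if (length(activations) == 1L) activations else
        sample(activations, 1L)
      out_name <- if (length(activations) == 1L) activations else
        sample(activations, 1L)
      hid <- act_fun(hid_name); outf <- act_fun(out_name)
      p <- length(candidates)
      w0 <- stats::rnorm(p * H + 2L * H + 1L, 0, 0.5 / sqrt(p))
      fit <- tryCatch(
        stats::optim(w0, mlp_sse, mlp_grad,
                     X = Z[tr_idx, , drop = FALSE], y = ys[tr_idx],
                     hid = hid, out = outf, method = "BFGS",
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) {
        message("network ", k, " (", hid_name, "/", out_name,
                ", H=", H, ") failed to train; discarded")
        return(NULL)
      }
      pr <- function(idx) mlp_forward(fit$par, Z[idx, , drop = FALSE],
                                      hid, outf)$yhat
      safe_cor <- function(a, b)
        if (length(a) >= 3 && stats::sd(a) > 0 && stats::sd(b) > 0)
          stats::cor(a, b) else NA_real_
      list(hidden = H, hidden_act = hid_name, output_act = out_name,
           weights = fit$par, sse = fit$value,
           cor_train = safe_cor(pr(tr_idx), ys[tr_idx]),
           cor_validation = safe_cor(pr(va_idx), ys[va_idx]),
           cor_test = if (length(te_idx))
             safe_cor(pr(te_idx), ys[te_idx]) else NA_real_)
    })
  })
  nets <- Filter(Negate(is.null), nets)
  if (!length(nets)) stop("no network trained successfully")
  val <- vapply(nets, function(n) n$cor_validation %||% NA_real_, numeric(1))
  val[is.na(val)] <- -Inf
  keep <- order(val, decreasing = TRUE)[seq_len(min(n_retain, length(nets)))]
  nets <- nets[keep]

  correlations <- data.frame(
    net = seq_along(nets),
    hidden = vapply(nets, `[[`, integer(1), "hidden"),
    hidden_act = vapply(nets, `[[`, character(1), "hidden_act"),
    output_act = vapply(nets, `[[`, character(1), "output_act"),
    cor_train = vapply(nets, `[[`, numeric(1), "cor_train"),
    cor_validation = vapply(nets, `[[`, numeric(1), "cor_validation"),
    cor_test = vapply(nets, `[[`, numeric(1), "cor_test"),
    stringsAsFactors = FALSE)

  structure(list(nets = nets, correlations = correlations,
                 candidates = candidates,
                 scaling = list(mu_x = mu_x, sd_x = sd_x,
                                mu_y = mu_y, sd_y = sd_y),
                 params = list(n_nets = n_nets, n_retain = n_retain,
                               seed = seed, carved_validation = carve)),
            class = "qsar_ann")
}

#' Predict from a neural-network ensemble
#'
#' @param object A `qsar_ann`.
#' @param newdata Descriptor data frame.
#' @param type `"matrix"` (default): one column per retained network;
#'   `"mean"`: ensemble mean vector.
#' @param ... Unused.
#' @return Matrix (rows = compounds, columns `ann1 ... annK`) or vector.
#' @export
predict.qsar_ann <- function(object, newdata, type = c("matrix", "mean"),
                             ...) {
  type <- match.arg(type)
  X <- descriptor_matrix(newdata, object$candidates)
  Z <- sweep(sweep(X, 2, object$scaling$mu_x), 2, object$scaling$sd_x, "/")
  preds <- vapply(object$nets, function(n) {
    yhat <- mlp_forward(n$weights, Z, act_fun(n$hidden_act),
                        act_fun(n$output_act))$yhat
    object$scaling$mu_y + object$scaling$sd_y * yhat
  }, numeric(nrow(Z)))
  preds <- matrix(preds, nrow = nrow(Z),
                  dimnames = list(newdata$id %||% NULL,
                                  paste0("ann", seq_along(object$nets))))
  if (type == "mean") rowMeans(preds) else preds
}

#' @export
print.qsar_ann <- function(x, ...) {
  cat("Neural-network ensemble:", length(x$nets), "retained of",
      x$params$n_nets, "trained\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Global sensitivity analysis by mean-substitution ablation
#'
#' Rates the importance of each input variable of a fitted regressor by
#' the ratio `SSR(model with the variable ablated) / SSR(full model)` on the
#' evaluation rows, where ablation replaces the variable by its
#' training-split mean (the model is not refit).  A score of 1 means the
#' ablation leaves predictions unchanged; scores at or below 1 mean the
#' model performs no worse without the variable.
#'
#' @param model Any fitted regressor with a `predict(model, newdata)`
#'   method (`qsar_model`, `qsar_mlr`, `qsar_bt`, `qsar_ann` — the ensemble
#'   mean is used for the last).
#' @param data A [qsar_data] object.
#' @param descriptors Variables to ablate; defaults to the model's inputs.
#' @param eval_split Split on which residuals are measured (default
#'   `"train"`).
#' @return Object of class `gsa_report`: data frame `descriptor`/`score`,
#'   sorted descending.  If the full model fits exactly (SSR = 0), scores
#'   are `Inf` with a warning.
#' @export
gsa <- function(model, data, descriptors = NULL, eval_split = "train") {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(descriptors)) descriptors <- model_inputs(model)
  pred_fun <- if (inherits(model, "qsar_ann"))
    function(nd) predict(model, nd, type = "mean") else
    function(nd) predict(model, nd)
  ev <- split_rows(data, eval_split)
  tr <- split_rows(data, "train")
  ssr_full <- sum((ev$response - pred_fun(ev$compounds))^2)
  warn0 <- ssr_full == 0
  if (warn0) warning("full model has zero residual sum of squares; ",
                     "GSA scores reported as Inf")
  scores <- vapply(descriptors, function(v) {
    nd <- ev$compounds
    nd[[v]] <- mean(tr$compounds[[v]])
    ssr_v <- sum((ev$response - pred_fun(nd))^2)
    if (warn0) Inf else ssr_v / ssr_full
  }, numeric(1))
  out <- data.frame(descriptor = descriptors, score = unname(scores),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  structure(out, class = c("gsa_report", "data.frame"))
}

# Input variables of a fitted model, by class.
model_inputs <- function(model) {
  if (inherits(model, "qsar_bt")) return(model$candidates)
  if (inherits(model, "qsar_ann")) return(model$candidates)
  if (inherits(model, "qsar_model")) return(names(model$coefficients))
  stop("cannot determine input variables for class ",
       paste(class(model), collapse = "/"))
}
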