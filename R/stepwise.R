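#' Tolerance-based collinearity screen
#'
#' For every pair of candidate descriptors, computes the tolerance
#' `1 - r^2` (r = Pearson correlation on the training split).  Pairs with
#' tolerance below `cutoff` are collinear; one member of each flagged pair
#' is dropped — the one with the smaller absolute correlation to the
#' response, ties broken by dropping the later in input order.
#' Zero-variance candidates are degenerate and dropped with a warning.
#'
#' @param data A [qsar_data] object with at least 3 training rows.
#' @param candidates Character vector of descriptor names to screen.
#' @param cutoff Tolerance below which a pair counts as collinear
#'   (default 0.1).
#' @return List with `retained` (character), `flagged_pairs` (data frame
#'   `a`/`b`/`tolerance`/`dropped`) and `degenerate` (character).
#' @examples
#' cfg <- synthetic_config("logKoc", n_train = 50, n_test = 0, seed = 1)
#' d <- gen_reference_dataset(cfg)
#' tolerance_screen(d, c("nRot", "nHet", "logP"))$retained
#' @export
tolerance_screen <- function(data, candidates, cutoff = 0.1) {
  stopifnot(inherits(data, "qsar_data"), length(candidates) >= 1)
  tr <- split_rows(data, "train")
  if (nrow(tr$compounds) < 3) stop("need at least 3 training rows")
  X <- descriptor_matrix(tr$compounds, candidates)
  y <- tr$response

  sds <- apply(X, 2, stats::sd)
  degenerate <- candidates[sds == 0]
  if (length(degenerate)) {
    warning("zero-variance candidate(s) dropped as degenerate: ",
            paste(degenerate, collapse = ", "))
    candidates <- setdiff(candidates, degenerate)
    X <- X[, candidates, drop = FALSE]
  }

  flagged <- data.frame(a = character(), b = character(),
                        tolerance = numeric(), dropped = character(),
                        stringsAsFactors = FALSE)
  retained <- candidates
  if (length(candidates) >= 2) {
    ry <- abs(stats::cor(X, y))[, 1L]
    rmat <- stats::cor(X)
    for (i in seq_len(length(candidates) - 1L)) {
      for (j in seq(i + 1L, length(candidates))) {
        a <- candidates[i]; b <- candidates[j]
        tol <- 1 - rmat[i, j]^2
        if (tol < cutoff) {
          # drop the member less correlated with the response;
          # ties drop the later in input order
          drop <- if (ry[a] > ry[b]) b else if (ry[b] > ry[a]) a else b
          flagged <- rbind(flagged,
                           data.frame(a = a, b = b, tolerance = tol,
                                      dropped = drop,
                                      stringsAsFactors = FALSE))
        }
      }
    }
    retained <- setdiff(candidates, unique(flagged$dropped))
  }
  list(retained = retained, flagged_pairs = flagged, degenerate = degenerate)
}

#' Forward stepwise multiple linear regression with QSAR validation
#'
#' The package's central fitting function.  Starting from an
#' intercept-only model, each step enters the candidate descriptor with the
#' largest partial F statistic, provided its p-value is below `p_enter`
#' (ties: larger F, then input order); there is no removal step.  The final
#' model is refit by ordinary least squares for coefficients and standard
#' errors, and validated with the QSAR canon: training R^2 and adjusted
#' R^2, leave-one-out Q^2 ([loo_q2()]) and, when a test split is present,
#' external RMSE of prediction ([rmse_pred()]).
#'
#' @param data A [qsar_data] object.
#' @param candidates Character vector of candidate descriptor names
#'   (normally the survivors of [tolerance_screen()]).
#' @param p_enter Entry significance threshold for the partial F test
#'   (default 0.05).
#' @return An object of classes `qsar_mlr` and `qsar_model`: the fitted
#'   equation (intercept, coefficients, standard errors) plus `step_trace`
#'   (data frame `step`/`descriptor`/`F`/`p`/`cum_R2`), `metrics`
#'   (`R2`, `R2adj`, `Q2`, `RMSE_pred`), `n_train`, `n_test` and the
#'   underlying `lm` fit.
#' @seealso [predict.qsar_model()], [summary.qsar_mlr()], [loo_q2()],
#'   [rmse_pred()]
#' @examples
#' cfg <- synthetic_config("logKoc", n_train = 120, n_test = 30, seed = 7)
#' d <- gen_reference_dataset(cfg)
#' fit <- qsar_stepwise(d, candidates = names(model_koc()$coefficients))
#' fit
#' @export
qsar_stepwise <- function(data, candidates, p_enter = 0.05) {
  stopifnot(inherits(data, "qsar_data"), length(candidates) >= 1,
            p_enter > 0, p_enter < 1)
  tr <- split_rows(data, "train")
  n <- nrow(tr$compounds)
  if (n <= length(candidates) + 2)
    stop("need n_train > length(candidates) + 2")
  X <- descriptor_matrix(tr$compounds, candidates)
  y <- tr$response
  tss <- sum((y - mean(y))^2)

  selected <- character()
  rss_cur <- tss
  trace <- data.frame(step = integer(), descriptor = character(),
                      F = numeric(), p = numeric(), cum_R2 = numeric(),
                      stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    p_cur <- length(selected)
    df2 <- n - p_cur - 2L          # residual df after entering one more term
    if (df2 <= 0) break
    best <- NULL
    for (cand in remaining) {
      Xc <- cbind(1, X[, c(selected, cand), drop = FALSE])
      fit <- stats::lm.fit(Xc, y)
      if (fit$rank < ncol(Xc))
        stop("design matrix rank-deficient when entering '", cand, "'")
      rss_new <- sum(fit$residuals^2)
      Fstat <- (rss_cur - rss_new) / (rss_new / df2)
      if (is.null(best) || Fstat > best$F)   # ties keep earlier candidate
        best <- list(cand = cand, F = Fstat, rss = rss_new)
    }
    pval <- stats::pf(best$F, 1, df2, lower.tail = FALSE)
    if (pval >= p_enter) break
    selected <- c(selected, best$cand)
    rss_cur <- best$rss
    trace <- rbind(trace, data.frame(step = length(selected),
                                     descriptor = best$cand, F = best$F,
                                     p = pval, cum_R2 = 1 - best$rss / tss,
                                     stringsAsFactors = FALSE))
  }

  # final OLS refit (with SEs) on the selected term set
  df_fit <- data.frame(.y = y, tr$compounds[, selected, drop = FALSE],
                       check.names = FALSE)
  form <- if (length(selected))
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", selected),
                                          collapse = " + ")))
  else stats::as.formula(".y ~ 1")
  lmfit <- stats::lm(form, data = df_fit)
  sm <- summary(lmfit)
  cf <- stats::coef(sm)
  coefs <- if (length(selected))
    stats::setNames(cf[selected, 1L], selected) else
    stats::setNames(numeric(0), character(0))
  ses <- if (length(selected))
    stats::setNames(cf[selected, 2L], selected) else NULL

  r2 <- sm$r.squared
  r2adj <- sm$adj.r.squared
  obj <- structure(
    list(property = data$property,
         intercept = unname(cf["(Intercept)", 1L]),
         coefficients = coefs,
         se = ses,
         intercept_se = unname(cf["(Intercept)", 2L]),
         provenance = sprintf("forward stepwise MLR fit (n_train = %d)", n),
         step_trace = trace,
         metrics = c(R2 = r2, R2adj = r2adj, Q2 = NA_real_,
                     RMSE_pred = NA_real_),
         n_train = n,
         n_test = sum(data$split == "test"),
         p_enter = p_enter,
         candidates = candidates,
         lm = lmfit),
    class = c("qsar_mlr", "qsar_model"))
  obj$metrics["Q2"] <- if (n >= 5) loo_q2(obj, data) else NA_real_
  if (obj$n_test > 0) obj$metrics["RMSE_pred"] <- rmse_pred(obj, data)
  obj
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2 = 1 - PRESS/TSS`, where PRESS is the sum of squared leave-one-out
#' prediction errors of the model's term set refit on the training split
#' with each row held out in turn, and TSS the total sum of squares about
#' the training mean.  For ordinary least squares the n refits reduce
#' exactly to the PRESS identity `e_i / (1 - h_ii)` (hat-matrix leverages),
#' which is what is computed; the naive n-refit loop gives identical values.
#'
#' @param model A `qsar_mlr`/`qsar_model` whose terms define the regression;
#'   the coefficients themselves are re-estimated per leave-one-out fold.
#' @param data A [qsar_data] with at least 5 training rows.
#' @return Q2 (at most 1; can be negative for non-predictive models).
#' @export
loo_q2 <- function(model, data) {
  stopifnot(inherits(model, "qsar_model"), inherits(data, "qsar_data"))
  tr <- split_rows(data, "train")
  n <- nrow(tr$compounds)
  if (n < 5) stop("need at least 5 training rows for LOO Q2")
  vars <- names(model$coefficients)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (length(vars)) X <- cbind(X, descriptor_matrix(tr$compounds, vars))
  y <- tr$response
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) stop("design matrix singular in LOO refit")
  fit <- stats::lm.fit(X, y)
  h <- rowSums(qr.Q(qr_)^2)
  if (any(h >= 1 - 1e-12)) {
    bad <- which(h >= 1 - 1e-12)[1L]
    stop("LOO refit singular when leaving out training row ", bad,
         " (id ", tr$compounds$id[bad] %||% bad, ")")
  }
  press <- sum((fit$residuals / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

#' External RMSE of prediction
#'
#' Root mean squared error of a model's predictions on the test split.
#'
#' @param model Any object with a `predict(model, newdata)` method returning
#'   numeric predictions (a `qsar_model`, `qsar_mlr`, `qsar_bt`, ...).
#' @param data A [qsar_data] with a non-empty test split.
#' @return Non-negative scalar, same (log10) units as the response.
#' @export
rmse_pred <- function(model, data) {
  stopifnot(inherits(data, "qsar_data"))
  te <- split_rows(data, "test")
  if (nrow(te$compounds) == 0) stop("test split is empty")
  pred <- predict(model, te$compounds)
  sqrt(mean((pred - te$response)^2))
}

#' @export
print.qsar_mlr <- function(x, digits = 4, ...) {
  cat("Forward stepwise MLR model of", x$property, "\n")
  cat("  n_train =", x$n_train, " n_test =", x$n_test,
      " p_enter =", x$p_enter, "\n")
  cf <- coef(x)
  se <- c(x$intercept_se, x$se)
  tab <- data.frame(coefficient = signif(cf, digits),
                    se = signif(se, digits), row.names = names(cf))
  print(tab)
  m <- x$metrics
  cat(sprintf("  R2 = %.4f  R2adj = %.4f  Q2 = %.4f  RMSE_pred = %s\n",
              m["R2"], m["R2adj"], m["Q2"],
              if (is.na(m["RMSE_pred"])) "NA" else
                sprintf("%.4f", m["RMSE_pred"])))
  invisible(x)
}

#' Summary of a stepwise MLR fit
#'
#' @param object A `qsar_mlr`.
#' @param ... Unused.
#' @return The object, invisibly; prints the coefficient table, the entry
#'   trace and the validation metrics.
#' @export
summary.qsar_mlr <- function(object, ...) {
  print(object)
  if (nrow(object$step_trace)) {
    cat("Entry trace:\n")
    print(object$step_trace, row.names = FALSE, digits = 4)
  } else cat("No descriptor met the entry criterion (intercept-only).\n")
  invisible(object)
}

#' @export
residuals.qsar_mlr <- function(object, ...) stats::residuals(object$lm)

#' Predicted-versus-observed plot for a stepwise MLR fit
#'
#' @param x A `qsar_mlr`.
#' @param data The [qsar_data] it was fit on.
#' @param split Which split to plot (default `"train"`).
#' @param ... Passed to [plot()].
#' @return Invisibly, a data frame of observed and predicted values.
#' @export
plot.qsar_mlr <- function(x, data, split = "train", ...) {
  s <- split_rows(data, split)
  pred <- predict(x, s$compounds)
  plot(s$response, pred,
       xlab = paste("observed", x$property),
       ylab = paste("predicted", x$property),
       main = sprintf("%s (%s split)", x$property, split), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(observed = s$response, predicted = pred))
}
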