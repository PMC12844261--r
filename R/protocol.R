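#' Default candidate descriptor sets per property
#'
#' The descriptor panels used for model development: rotatable bonds,
#' heteroatoms, rings, PAMPA, log S and log P for log Koc; log D, log S,
#' rotatable bonds, PAMPA and largest-ring size for log BCF; TPSA, MDCK,
#' heteroatoms and Fsp3 for log Kp,uu (the boosted-tree stage for log Kp,uu
#' additionally uses logVDss).
#'
#' @param property One of `"logKoc"`, `"logBCF"`, `"logKpuu"`.
#' @return Character vector of descriptor names.
#' @export
default_candidates <- function(property) {
  switch(match.arg(property, c("logKoc", "logBCF", "logKpuu")),
         logKoc = c("nRot", "nHet", "nRing", "PAMPA", "logS", "logP"),
         logBCF = c("nRot", "MaxRing", "PAMPA", "logS", "logD"),
         logKpuu = c("TPSA", "nHet", "Fsp3", "MDCK"))
}

#' Run the full model-development protocol on a reference dataset
#'
#' End-to-end driver: tolerance-based collinearity screen, forward stepwise
#' MLR with LOO-Q2 and external-RMSE validation, a boosted-tree model with
#' relative importances, a neural-network ensemble (on the MLR-selected
#' variables, mirroring the convention that the ANN stage uses the same
#' independent variables as the MLR stage), and a global sensitivity
#' analysis of the network ensemble.  For log Kp,uu the boosted-tree stage
#' additionally includes `logVDss` when the table provides it.
#'
#' @param data A [qsar_data] object.
#' @param config List of options: `candidates` (default
#'   [default_candidates()] for the dataset's property), `p_enter` (0.05),
#'   `tolerance_cutoff` (0.1), `seed` (1), `bt` (list of [qsar_bt()]
#'   parameters, or `FALSE` to skip), `ann` (list of [qsar_ann()]
#'   parameters, or `FALSE` to skip).
#' @return Object of class `qsar_protocol`: list with `screen`, `mlr`,
#'   `bt`, `ann`, `gsa`, `config`.  Deterministic under `config$seed`.
#' @examples
#' cfg <- synthetic_config("logKpuu", n_train = 60, n_test = 14, seed = 5)
#' d <- gen_reference_dataset(cfg)
#' b <- run_protocol(d, config = list(seed = 5, ann = list(n_nets = 4),
#'                                    bt = list(n_trees = 40)))
#' b$mlr$metrics
#' @export
run_protocol <- function(data, config = list()) {
  stopifnot(inherits(data, "qsar_data"))
  candidates <- config$candidates %||% default_candidates(data$property)
  if (!length(candidates)) stop("candidate descriptor list is empty")
  p_enter <- config$p_enter %||% 0.05
  cutoff <- config$tolerance_cutoff %||% 0.1
  seed <- config$seed %||% 1

  screen <- tolerance_screen(data, candidates, cutoff = cutoff)
  if (!length(screen$retained))
    stop("no candidate descriptor survived the collinearity screen")
  mlr <- qsar_stepwise(data, screen$retained, p_enter = p_enter)

  bt <- NULL
  if (!isFALSE(config$bt)) {
    btc <- if (is.list(config$bt)) config$bt else list()
    bt_cands <- screen$retained
    if (data$property == "logKpuu" &&
        "logVDss" %in% names(data$compounds))
      bt_cands <- union(bt_cands, "logVDss")
    bt <- qsar_bt(data, bt_cands,
                  n_trees = btc$n_trees %||% 200,
                  depth = btc$depth %||% 3,
                  learning_rate = btc$learning_rate %||% 0.05,
                  seed = seed)
  }

  ann <- NULL
  if (!isFALSE(config$ann)) {
    annc <- if (is.list(config$ann)) config$ann else list()
    ann_cands <- names(mlr$coefficients)
    if (!length(ann_cands)) ann_cands <- screen$retained
    ann <- qsar_ann(data, ann_cands,
                    n_nets = annc$n_nets %||% 50,
                    n_retain = annc$n_retain %||% 5,
                    hidden_range = annc$hidden_range %||% 2:8,
                    activations = annc$activations %||%
                      c("identity", "logistic", "tanh", "exponential"),
                    seed = seed,
                    maxit = annc$maxit %||% 300)
  }

  sens <- gsa(if (!is.null(ann)) ann else mlr, data)

  structure(list(screen = screen, mlr = mlr, bt = bt, ann = ann,
                 gsa = sens,
                 config = list(candidates = candidates, p_enter = p_enter,
                               tolerance_cutoff = cutoff, seed = seed)),
            class = "qsar_protocol")
}

#' @export
print.qsar_protocol <- function(x, ...) {
  cat("== QSAR model-development protocol ==\n")
  if (nrow(x$screen$flagged_pairs)) {
    cat("Collinearity screen flagged:\n")
    print(x$screen$flagged_pairs, row.names = FALSE, digits = 3)
  } else cat("Collinearity screen: no pair flagged\n")
  print(x$mlr)
  if (!is.null(x$bt)) print(x$bt)
  if (!is.null(x$ann)) print(x$ann)
  cat("Global sensitivity analysis:\n")
  print(as.data.frame(x$gsa), row.names = FALSE, digits = 3)
  invisible(x)
}
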