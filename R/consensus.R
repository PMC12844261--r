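#' Pearson correlation matrix across model predictions
#'
#' Cross-model agreement: given one prediction vector per model, aligned by
#' compound, returns the symmetric matrix of pairwise Pearson correlation
#' coefficients with unit diagonal.  A zero-variance prediction vector has
#' no defined correlation; its row and column are reported as `NA` with a
#' warning, never silently dropped.
#'
#' @param predictions Named list (or matrix with named columns) of numeric
#'   vectors, one per model, all the same length >= 3.
#' @return Symmetric numeric matrix with model labels as dimnames.
#' @examples
#' pearson_matrix(list(MLR = c(1, 2, 3), BT = c(1.1, 2.2, 2.9)))
#' @export
pearson_matrix <- function(predictions) {
  if (is.matrix(predictions) || is.data.frame(predictions))
    predictions <- as.list(as.data.frame(predictions))
  stopifnot(is.list(predictions), length(predictions) >= 2,
            !is.null(names(predictions)))
  lens <- lengths(predictions)
  if (length(unique(lens)) != 1L || lens[1L] < 3)
    stop("all prediction vectors must have the same length >= 3")
  P <- do.call(cbind, predictions)
  degenerate <- names(predictions)[apply(P, 2, stats::sd) == 0]
  if (length(degenerate))
    warning("zero-variance prediction vector(s), correlations undefined: ",
            paste(degenerate, collapse = ", "))
  M <- suppressWarnings(stats::cor(P))
  diag(M) <- 1
  M[degenerate, ] <- NA_real_
  M[, degenerate] <- NA_real_
  diag(M)[colnames(M) %in% degenerate] <- NA_real_
  M
}

#' Consensus prediction across models
#'
#' Per-compound arithmetic mean, spread (standard deviation) and range of
#' the predictions of two or more models.  A compound missing a prediction
#' in any model is flagged and excluded from the consensus statistics.
#'
#' @param predictions Named list of numeric vectors (one per model, aligned
#'   by compound), or a matrix/data frame with one column per model; row
#'   names or an `id` attribute supply compound ids when available.
#' @param ids Optional compound ids.
#' @return Data frame: `id`, `mean`, `sd`, `min`, `max`, `n_models`,
#'   `flagged` (TRUE where any model's prediction is missing; statistics
#'   `NA` there).
#' @export
consensus_predict <- function(predictions, ids = NULL) {
  if (is.list(predictions) && !is.data.frame(predictions))
    predictions <- do.call(cbind, predictions)
  P <- as.matrix(predictions)
  if (ncol(P) < 2) stop("need at least 2 models for a consensus")
  if (is.null(ids))
    ids <- rownames(P) %||% as.character(seq_len(nrow(P)))
  flagged <- apply(P, 1, anyNA)
  stat <- function(f) {
    v <- apply(P, 1, f)
    v[flagged] <- NA_real_
    v
  }
  data.frame(id = ids,
             mean = stat(mean), sd = stat(stats::sd),
             min = stat(min), max = stat(max),
             n_models = ncol(P), flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-family summary of a predicted or observed property
#'
#' Groups compounds by chemical family and summarizes a per-compound value
#' (n, mean, median, quartiles, range), the numbers behind per-family
#' violin plots.  Families with no compounds are omitted.
#'
#' @param records Data frame with `id` and `family` columns.
#' @param values Numeric vector named by compound id (or in row order).
#' @return List with `summary` (data frame, one row per family, sorted by
#'   descending mean) and `values` (named list of per-family value vectors,
#'   e.g. for violin plots).
#' @export
family_summary <- function(records, values) {
  stopifnot(is.data.frame(records), "id" %in% names(records),
            "family" %in% names(records))
  ids <- as.character(records$id)
  v <- if (!is.null(names(values))) {
    missing <- setdiff(ids, names(values))
    if (length(missing))
      stop("no value for id(s): ", paste(missing, collapse = ", "))
    values[ids]
  } else {
    stopifnot(length(values) == length(ids))
    stats::setNames(values, ids)
  }
  fam <- as.character(records$family)
  groups <- split(v, fam)
  rows <- lapply(names(groups), function(f) {
    x <- groups[[f]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(family = f, n = length(x), mean = mean(x),
               min = min(x), q1 = q[1], median = q[2], q3 = q[3],
               max = max(x), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary <- summary[order(-summary$mean), ]
  rownames(summary) <- NULL
  list(summary = summary, values = groups)
}

#' Applicability-domain range check
#'
#' Compares query compounds with the descriptor ranges spanned by the
#' reference (training) compounds: for each descriptor, the reference
#' min/max, the fraction of query compounds inside that range, and the
#' out-of-range compound ids; plus a per-compound in-domain flag (inside
#' the reference range for every checked descriptor).  Range coverage is
#' the domain notion used here; leverage- or distance-based domains are out
#' of scope.
#'
#' @param reference A [qsar_data] object or descriptor data frame.
#' @param query Data frame of query compounds with an `id` column.
#' @param descriptors Descriptor names to check.
#' @return List with `per_descriptor` (data frame `descriptor`/`ref_min`/
#'   `ref_max`/`coverage`/`out_of_range` ids collapsed with ";") and
#'   `per_compound` (data frame `id`/`in_domain`).  An empty query yields
#'   empty report components, no error.
#' @export
applicability_check <- function(reference, query, descriptors) {
  ref <- if (inherits(reference, "qsar_data")) reference$compounds else
    reference
  stopifnot(is.data.frame(ref), is.data.frame(query))
  missing_ref <- setdiff(descriptors, names(ref))
  if (length(missing_ref))
    stop("descriptor(s) absent from reference: ",
         paste(missing_ref, collapse = ", "))
  if (nrow(query)) {
    missing_q <- setdiff(descriptors, names(query))
    if (length(missing_q))
      stop("descriptor(s) absent from query: ",
           paste(missing_q, collapse = ", "))
  }
  qids <- if ("id" %in% names(query)) as.character(query$id) else
    as.character(seq_len(nrow(query)))
  in_range <- matrix(TRUE, nrow(query), length(descriptors),
                     dimnames = list(qids, descriptors))
  per_desc <- lapply(descriptors, function(d) {
    lo <- min(ref[[d]]); hi <- max(ref[[d]])
    inside <- if (nrow(query)) query[[d]] >= lo & query[[d]] <= hi else
      logical(0)
    if (nrow(query)) in_range[, d] <<- inside
    data.frame(descriptor = d, ref_min = lo, ref_max = hi,
               coverage = if (nrow(query)) mean(inside) else NA_real_,
               out_of_range = paste(qids[!inside], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  list(per_descriptor = do.call(rbind, per_desc),
       per_compound = data.frame(id = qids,
                                 in_domain = if (nrow(query))
                                   apply(in_range, 1, all) else logical(0),
                                 stringsAsFactors = FALSE, row.names = NULL))
}
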