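#' Reference dataset for QSAR model development
#'
#' Bundles a compound descriptor table with an observed log10 property and a
#' train/test(/validation) split, the unit every fitting routine consumes.
#'
#' @param compounds Data frame with an `id` column and descriptor columns.
#' @param response Numeric vector of observed property values (log10 units),
#'   either named by compound id or in row order.
#' @param split Character vector of `"train"`, `"test"`, `"validation"`,
#'   named by id or in row order; must cover every compound.
#' @param property One of `"logKoc"`, `"logBCF"`, `"logKpuu"`.
#' @return Object of class `qsar_data`: list with `compounds`, `response`,
#'   `split` (both named by id) and `property`.
#' @export
qsar_data <- function(compounds, response, split, property) {
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds))
  property <- match.arg(property, c("logKoc", "logBCF", "logKpuu"))
  ids <- as.character(compounds$id)
  if (anyDuplicated(ids)) stop("duplicate compound ids")
  align <- function(x, what) {
    if (!is.null(names(x))) {
      missing <- setdiff(ids, names(x))
      if (length(missing))
        stop(what, " not defined for id(s): ",
             paste(missing, collapse = ", "))
      x[ids]
    } else {
      if (length(x) != length(ids))
        stop(what, " must have one value per compound")
      stats::setNames(x, ids)
    }
  }
  response <- align(response, "response")
  split <- align(as.character(split), "split")
  bad <- setdiff(unique(split), c("train", "test", "validation"))
  if (length(bad))
    stop("split labels must be train/test/validation; got: ",
         paste(bad, collapse = ", "))
  if (anyNA(response)) stop("response contains missing values")
  structure(list(compounds = compounds, response = response, split = split,
                 property = property),
            class = "qsar_data")
}

#' @export
print.qsar_data <- function(x, ...) {
  cat("QSAR reference dataset:", x$property, "\n")
  cat("  ", nrow(x$compounds), " compounds (",
      paste(names(table(x$split)), table(x$split),
            sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("  descriptors:",
      paste(descriptor_columns(x$compounds), collapse = ", "), "\n")
  invisible(x)
}

# Rows of a given split, as (X data.frame rows, y) pieces.
split_rows <- function(data, which = "train") {
  stopifnot(inherits(data, "qsar_data"))
  idx <- data$split %in% which
  list(compounds = data$compounds[idx, , drop = FALSE],
       response = data$response[idx])
}
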