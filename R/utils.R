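# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package take an explicit seed and route
# through this, so no function perturbs the global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Extract a descriptor matrix (rows = compounds) from a data frame,
# erroring per missing column/value with the compound id in the message.
descriptor_matrix <- function(records, vars) {
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("missing descriptor column(s): ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(records[, vars, drop = FALSE])
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    ids <- if ("id" %in% names(records)) records$id[bad[, 1L]] else bad[, 1L]
    stop("missing descriptor value(s): ",
         paste(unique(paste0(ids, ":", vars[bad[, 2L]])), collapse = ", "))
  }
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
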