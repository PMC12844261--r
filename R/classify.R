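#' EPA soil mobility class from log Koc
#'
#' Assigns the EPA soil mobility category.  The published class table lists
#' touching ranges ("1-2", "2-3", ...); boundaries are taken as
#' lower-inclusive half-open intervals, so exactly 2.0 is "moderately
#' mobile": `<1` very_mobile, `[1,2)` mobile, `[2,3)` moderately_mobile,
#' `[3,4)` slightly_mobile, `[4,5)` hardly_mobile, `>=5` immobile.
#'
#' @param log_koc Numeric vector of log10 Koc values; must be finite.
#' @return Ordered factor with levels from `very_mobile` to `immobile`.
#' @examples
#' classify_mobility(c(0.5, 2.485, 5.5))
#' @export
classify_mobility <- function(log_koc) {
  if (any(!is.finite(log_koc))) stop("log_koc must be finite")
  lev <- c("very_mobile", "mobile", "moderately_mobile",
           "slightly_mobile", "hardly_mobile", "immobile")
  idx <- findInterval(log_koc, c(1, 2, 3, 4, 5)) + 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Bioaccumulation flag from log BCF
#'
#' Regulatory cut-offs for bioaccumulation in fish differ between bodies;
#' the two in use are log BCF > 3.3 and > 3.7.  The conservative 3.3 is the
#' default; 3.7 is selectable.  The comparison is strict: a compound exactly
#' at the threshold is not flagged.
#'
#' @param log_bcf Numeric vector of log10 BCF values; must be finite.
#' @param threshold Cut-off, normally 3.3 or 3.7; other values are accepted
#'   with a warning.
#' @return Data frame with columns `bioaccumulative` (logical) and
#'   `threshold` (the cut-off applied, recorded per row).
#' @export
flag_bioaccumulation <- function(log_bcf, threshold = 3.3) {
  if (any(!is.finite(log_bcf))) stop("log_bcf must be finite")
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (!threshold %in% c(3.3, 3.7))
    warning("non-standard bioaccumulation threshold ", threshold,
            " (regulatory cut-offs are 3.3 and 3.7)")
  data.frame(bioaccumulative = log_bcf > threshold, threshold = threshold)
}

#' Blood-brain barrier category from log Kp,uu
#'
#' Literature cut-offs for free brain penetration span Kp,uu 0.3-0.5
#' (log Kp,uu -0.52 to -0.3); values below -2 indicate very poor brain
#' entry.  Bands (right-inclusive at the documented edges): `high` if
#' > -0.3; `moderate` in (-0.52, -0.3]; `low` in (-2, -0.52]; `very_low`
#' if <= -2.
#'
#' @param log_kpuu Numeric vector of log10 Kp,uu values; must be finite.
#' @return Ordered factor `very_low < low < moderate < high`.
#' @examples
#' classify_bbb(c(-0.1, -0.4, -2.5))
#' @export
classify_bbb <- function(log_kpuu) {
  if (any(!is.finite(log_kpuu))) stop("log_kpuu must be finite")
  lev <- c("very_low", "low", "moderate", "high")
  idx <- ifelse(log_kpuu > -0.3, 4L,
         ifelse(log_kpuu > -0.52, 3L,
         ifelse(log_kpuu > -2, 2L, 1L)))
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Human intestinal absorption flag
#'
#' A compound is considered absorbable from the GI tract when its predicted
#' HIA strictly exceeds the 30% cut-off.
#'
#' @param hia_percent Predicted human intestinal absorption, percent of oral
#'   dose; must lie in \[0, 100\].
#' @return Logical vector.
#' @export
flag_hia <- function(hia_percent) {
  if (any(!is.finite(hia_percent) | hia_percent < 0 | hia_percent > 100))
    stop("hia_percent must lie in [0, 100]")
  hia_percent > 30
}

#' Caco-2 permeability flag
#'
#' Predicted Caco-2 log permeabilities at or above -5.15 log units indicate
#' adequate permeability.  Values just under the cut-off are distinguished
#' from clearly impaired ones: `permeable` if >= -5.15; `borderline` in
#' \[-5.5, -5.15); `impaired` if < -5.5.
#'
#' @param caco2 Predicted Caco-2 log permeability; must be finite.
#' @return Ordered factor `impaired < borderline < permeable`.
#' @export
flag_caco2 <- function(caco2) {
  if (any(!is.finite(caco2))) stop("caco2 must be finite")
  lev <- c("impaired", "borderline", "permeable")
  idx <- ifelse(caco2 >= -5.15, 3L, ifelse(caco2 >= -5.5, 2L, 1L))
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Lipinski rule-of-five check
#'
#' Counts violations among MLOGP > 4.15, MW > 500, nHA > 10 and nHD > 5; a
#' compound is drug-like with at most one violation.  MW and MLOGP are
#' required; the H-bond rules are skipped (and the skip recorded) when nHA or
#' nHD is absent — absence is never treated as zero.
#'
#' @param d Named numeric vector or one-row data frame of descriptors.
#' @return List with `violations` (integer), `drug_like` (logical) and
#'   `skipped` (character vector of rules not evaluated).
#' @examples
#' ro5_check(c(MLOGP = 4.89, MW = 511))   # lufenuron-like: 2 violations
#' @export
ro5_check <- function(d) {
  if (is.data.frame(d)) {
    stopifnot(nrow(d) == 1L)
    d <- unlist(d[, descriptor_columns(d), drop = FALSE])
  }
  get <- function(nm) if (nm %in% names(d) && !is.na(d[[nm]])) d[[nm]] else NULL
  mw <- get("MW"); mlogp <- get("MLOGP")
  if (is.null(mw) || is.null(mlogp))
    stop("ro5_check requires MW and MLOGP")
  violations <- (mlogp > 4.15) + (mw > 500)
  skipped <- character()
  nha <- get("nHA"); nhd <- get("nHD")
  if (is.null(nha)) skipped <- c(skipped, "nHA > 10") else
    violations <- violations + (nha > 10)
  if (is.null(nhd)) skipped <- c(skipped, "nHD > 5") else
    violations <- violations + (nhd > 5)
  list(violations = as.integer(violations),
       drug_like = violations <= 1L,
       skipped = skipped)
}

#' Consolidated risk classification for one compound
#'
#' Composes the individual threshold classifiers into a single record:
#' soil mobility from the predicted log Koc, bioaccumulation from log BCF,
#' blood-brain barrier category from log Kp,uu, the HIA and Caco-2 flags and
#' the rule-of-five check from the descriptors.  Deterministic; a requested
#' check whose input is absent is an error naming the missing quantity.
#'
#' @param d Named numeric vector or one-row data frame of descriptors
#'   (needs `HIA`, `caco2`, `MW`, `MLOGP` for the corresponding checks).
#' @param predictions Named numeric vector of predicted properties
#'   (`logKoc`, `logBCF`, `logKpuu` as needed).
#' @param checks Character vector of checks to run; default all.
#' @param bcf_threshold Bioaccumulation cut-off, 3.3 (default) or 3.7.
#' @return One-row data frame (class `qsar_classification`) with columns
#'   `mobility_class`, `bioaccumulative`, `bcf_threshold`, `bbb_category`,
#'   `hia_flag`, `caco2_flag`, `ro5_violations`, `drug_like`; checks not
#'   requested are `NA`.
#' @export
classify_compound <- function(d, predictions,
                              checks = c("mobility", "bioaccumulation",
                                         "bbb", "hia", "caco2", "ro5"),
                              bcf_threshold = 3.3) {
  checks <- match.arg(checks, several.ok = TRUE)
  if (is.data.frame(d)) {
    stopifnot(nrow(d) == 1L)
    dd <- unlist(d[, descriptor_columns(d), drop = FALSE])
  } else dd <- d
  need_pred <- function(nm) {
    if (!nm %in% names(predictions) || is.na(predictions[[nm]]))
      stop("prediction '", nm, "' required but not supplied")
    predictions[[nm]]
  }
  need_desc <- function(nm) {
    if (!nm %in% names(dd) || is.na(dd[[nm]]))
      stop("descriptor '", nm, "' required but not supplied")
    dd[[nm]]
  }
  out <- data.frame(mobility_class = NA_character_,
                    bioaccumulative = NA, bcf_threshold = NA_real_,
                    bbb_category = NA_character_, hia_flag = NA,
                    caco2_flag = NA_character_,
                    ro5_violations = NA_integer_, drug_like = NA,
                    stringsAsFactors = FALSE)
  if ("mobility" %in% checks)
    out$mobility_class <- as.character(classify_mobility(need_pred("logKoc")))
  if ("bioaccumulation" %in% checks) {
    b <- flag_bioaccumulation(need_pred("logBCF"), bcf_threshold)
    out$bioaccumulative <- b$bioaccumulative
    out$bcf_threshold <- b$threshold
  }
  if ("bbb" %in% checks)
    out$bbb_category <- as.character(classify_bbb(need_pred("logKpuu")))
  if ("hia" %in% checks)
    out$hia_flag <- flag_hia(need_desc("HIA"))
  if ("caco2" %in% checks)
    out$caco2_flag <- as.character(flag_caco2(need_desc("caco2")))
  if ("ro5" %in% checks) {
    r5 <- ro5_check(dd)
    out$ro5_violations <- r5$violations
    out$drug_like <- r5$drug_like
  }
  class(out) <- c("qsar_classification", class(out))
  out
}

#' Classify every compound in a table
#'
#' Vectorized driver over [classify_compound()]: takes a descriptor table
#' and a prediction table aligned by `id` and returns one classification row
#' per compound.  A compound failing a check (missing input) is reported in
#' the `error` column rather than aborting the whole table.
#'
#' @param records Descriptor data frame with an `id` column.
#' @param predictions Data frame with `id` and any of `logKoc`, `logBCF`,
#'   `logKpuu`.
#' @inheritParams classify_compound
#' @return Data frame: `id`, classification columns, `error`.
#' @export
classify_table <- function(records, predictions,
                           checks = c("mobility", "bioaccumulation",
                                      "bbb", "hia", "caco2", "ro5"),
                           bcf_threshold = 3.3) {
  stopifnot("id" %in% names(records), "id" %in% names(predictions))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    p <- predictions[match(id, predictions$id), , drop = FALSE]
    pv <- unlist(p[, setdiff(names(p), "id"), drop = FALSE])
    res <- tryCatch(
      cbind(data.frame(id = id, stringsAsFactors = FALSE),
            classify_compound(records[i, , drop = FALSE], pv,
                              checks = checks,
                              bcf_threshold = bcf_threshold),
            data.frame(error = NA_character_, stringsAsFactors = FALSE)),
      error = function(e)
        data.frame(id = id, mobility_class = NA_character_,
                   bioaccumulative = NA, bcf_threshold = NA_real_,
                   bbb_category = NA_character_, hia_flag = NA,
                   caco2_flag = NA_character_, ro5_violations = NA_integer_,
                   drug_like = NA, error = conditionMessage(e),
                   stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
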