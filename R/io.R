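#' Read a compound descriptor table from CSV/TSV
#'
#' Reads a UTF-8 delimited file with a header row, one compound per row:
#' metadata columns (`id`, optionally `name`, `family`, `smiles`) followed by
#' descriptor columns named exactly as in [descriptor_registry()].  Unicode
#' minus signs (U+2212) and en/em dashes in numeric cells are normalized to
#' ASCII hyphen-minus before parsing, so values pasted from typeset documents
#' parse correctly.  Columns whose names are not in the registry are kept as
#' opaque extras with a warning.
#'
#' @param path Path to the file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A data frame, one row per compound.
#' @seealso [write_compound_table()] for the lossless inverse.
#' @export
read_compound_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           comment.char = "")
  if (!"id" %in% names(raw)) stop("header must contain an 'id' column: ", path)
  extras <- setdiff(descriptor_columns(raw), descriptor_registry()$name)
  if (length(extras))
    warning("unrecognized descriptor column(s) carried as-is: ",
            paste(extras, collapse = ", "))
  out <- raw
  for (col in descriptor_columns(raw)) {
    txt <- normalize_minus(raw[[col]])
    txt[txt == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) & !is.na(txt))
    if (length(bad))
      stop(sprintf("malformed number %s in column '%s', data row %d of %s",
                   dQuote(txt[bad[1L]]), col, bad[1L], path))
    out[[col]] <- num
  }
  out
}

# Typographic minus/dash variants -> ASCII hyphen-minus.
normalize_minus <- function(x) {
  gsub("[−–—]", "-", x)
}

#' Write a compound descriptor table to CSV/TSV
#'
#' Numeric cells are written with 17 significant digits so that
#' write-then-read round-trips every double bit-exactly.
#'
#' @param records Data frame as returned by [read_compound_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(records, path, sep = ",") {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      txt <- vapply(out[[col]], function(v) {
        if (is.na(v)) "" else sprintf("%.17g", v)
      }, character(1))
      out[[col]] <- txt
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
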