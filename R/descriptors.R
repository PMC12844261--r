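#' Registry of recognized molecular and membrane-permeability descriptors
#'
#' The package works on tables of pre-computed descriptors (one row per
#' compound); it never derives descriptors from structures.  This registry
#' defines the recognized descriptor names, their value type and units, and
#' drives range/type validation in [validate_table()].
#'
#' Types are: `count` (non-negative integer), `unit` (value in \[0, 1\]),
#' `percent` (value in \[0, 100\]) and `real` (any finite real).
#'
#' @return A data frame with columns `name`, `type`, `units`.
#' @examples
#' head(descriptor_registry())
#' @export
descriptor_registry <- function() {
  reg <- rbind(
    c("MW",         "real",    "g/mol"),
    c("Vol",        "real",    "A^3 (van der Waals volume)"),
    c("Dense",      "real",    "g/mol/A^3 (MW/Vol)"),
    c("nHA",        "count",   "H-bond acceptors"),
    c("nHD",        "count",   "H-bond donors"),
    c("nRot",       "count",   "rotatable bonds"),
    c("nRing",      "count",   "rings"),
    c("MaxRing",    "count",   "atoms in largest ring"),
    c("nHet",       "count",   "non-carbon atoms"),
    c("nRig",       "count",   "rigid bonds"),
    c("Flex",       "real",    "nRot/nRig"),
    c("logS",       "real",    "log10 mol/L"),
    c("logP",       "real",    "log10"),
    c("logD",       "real",    "log10 at pH 7.4"),
    c("Fsp3",       "unit",    "fraction sp3 carbons"),
    c("TPSA",       "real",    "A^2"),
    c("caco2",      "real",    "log10 Papp"),
    c("MDCK",       "real",    "log10 Papp"),
    c("PAMPA",      "unit",    "probability of high permeability"),
    c("logVDss",    "real",    "log10 L/kg"),
    c("PPB",        "percent", "% plasma protein bound"),
    c("Fu",         "percent", "% unbound in plasma"),
    c("HIA",        "percent", "% absorbed"),
    c("MLOGP",      "real",    "log10 (Moriguchi)"),
    c("HeavyAtoms", "count",   "heavy atoms"),
    c("HBD",        "count",   "H-bond donors"),
    c("MR",         "real",    "molar refractivity"),
    c("iLOGP",      "real",    "log10 (iLOGP)")
  )
  data.frame(name = reg[, 1], type = reg[, 2], units = reg[, 3],
             stringsAsFactors = FALSE)
}

#' Controlled vocabulary of antiparasitic chemical families
#'
#' @return Character vector of recognized family tags.
#' @export
family_levels <- function() {
  c("benzimidazole", "organophosphate", "pyrethroid",
    "salicylanilide", "sulfonamide", "other")
}

# Columns of a compound table that are metadata, not descriptors.
meta_columns <- function() c("id", "name", "family", "smiles")

# Tolerance for the Dense = MW/Vol and Flex = nRot/nRig consistency checks.
RATIO_TOL <- 1e-9

descriptor_columns <- function(records) {
  setdiff(names(records), meta_columns())
}

check_value <- function(name, value, type) {
  if (is.na(value)) return("missing")
  if (!is.numeric(value) || !is.finite(value)) return("not a finite number")
  switch(type,
    count   = if (value < 0 || abs(value - round(value)) > 1e-8)
                "count must be a non-negative integer" else NA_character_,
    unit    = if (value < 0 || value > 1)
                "must lie in [0, 1]" else NA_character_,
    percent = if (value < 0 || value > 100)
                "must lie in [0, 100]" else NA_character_,
    real    = NA_character_
  )
}

#' Validate a compound descriptor table
#'
#' Checks a table of compound records against the descriptor registry:
#' duplicate ids are a hard error; for each record, required descriptors must
#' be present, every recognized descriptor must satisfy its type/range
#' invariant, and the derived ratios `Dense = MW/Vol` and `Flex = nRot/nRig`
#' must agree with their constituents to within 1e-9 when all are present.
#' Missing values are never imputed: a record failing any check is marked
#' unusable.
#'
#' @param records Data frame with columns `id` (required), optionally `name`,
#'   `family`, `smiles`, and descriptor columns named as in
#'   [descriptor_registry()].
#' @param required Character vector of descriptor names that every record
#'   must provide.
#' @return An object of class `qsar_validation`: a list with `pass` (logical
#'   scalar), `issues` (data frame `id`/`descriptor`/`problem`) and `usable`
#'   (named logical per record).
#' @examples
#' tab <- data.frame(id = c("a", "b"), nRot = c(3, 5), PAMPA = c(0.2, 1.3))
#' v <- validate_table(tab, required = c("nRot", "PAMPA"))
#' v$pass
#' @export
validate_table <- function(records, required = character()) {
  stopifnot(is.data.frame(records))
  if (!"id" %in% names(records)) stop("compound table must have an 'id' column")
  ids <- as.character(records$id)
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if ("family" %in% names(records)) {
    bad <- setdiff(unique(as.character(records$family)), family_levels())
    if (length(bad))
      stop("unknown family tag(s): ", paste(bad, collapse = ", "),
           "; recognized: ", paste(family_levels(), collapse = ", "))
  }
  reg <- descriptor_registry()
  desc_cols <- descriptor_columns(records)
  known <- intersect(desc_cols, reg$name)

  issues <- list()
  note <- function(id, descriptor, problem) {
    issues[[length(issues) + 1L]] <<-
      data.frame(id = id, descriptor = descriptor, problem = problem,
                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    id <- ids[i]
    for (d in setdiff(required, desc_cols))
      note(id, d, "required descriptor column absent")
    for (d in intersect(required, desc_cols))
      if (is.na(records[[d]][i])) note(id, d, "required descriptor missing")
    for (d in known) {
      v <- records[[d]][i]
      if (is.na(v)) next
      type <- reg$type[match(d, reg$name)]
      prob <- check_value(d, v, type)
      if (!is.na(prob)) note(id, d, prob)
    }
    # consistency of derived ratios with their constituents
    if (all(c("Dense", "MW", "Vol") %in% desc_cols)) {
      dn <- records$Dense[i]; mw <- records$MW[i]; vol <- records$Vol[i]
      if (!anyNA(c(dn, mw, vol)) && vol != 0 &&
          abs(dn - mw / vol) > RATIO_TOL)
        note(id, "Dense", "Dense differs from MW/Vol by more than 1e-9")
    }
    if (all(c("Flex", "nRot", "nRig") %in% desc_cols)) {
      fx <- records$Flex[i]; nr <- records$nRot[i]; ng <- records$nRig[i]
      if (!anyNA(c(fx, nr, ng)) && ng != 0 &&
          abs(fx - nr / ng) > RATIO_TOL)
        note(id, "Flex", "Flex differs from nRot/nRig by more than 1e-9")
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(id = character(), descriptor = character(),
               problem = character(), stringsAsFactors = FALSE)
  usable <- !(ids %in% issues$id)
  names(usable) <- ids
  structure(list(pass = nrow(issues) == 0L, issues = issues, usable = usable),
            class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat("Compound table validation:",
      if (x$pass) "PASS" else "FAIL", "\n")
  cat(sum(x$usable), "of", length(x$usable), "records usable\n")
  if (nrow(x$issues)) {
    cat("Issues:\n")
    print(x$issues, row.names = FALSE)
  }
  invisible(x)
}
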