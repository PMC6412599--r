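#' Patient-case fields and their domains
#'
#' A synthetic patient case assigns a value to every decision point the
#' guideline or the advisor may consult. Cases are carried as data.frames
#' with one row per case and one column per field (`case_id` first).
#'
#' `field_domains()` returns the allowed values for every finite-domain
#' field; continuous fields (`age`, `functional_status`) map to `NULL` and
#' are range-checked instead.
#'
#' @return `case_fields()`: character vector of all field names in canonical
#'   order. `field_domains()`: named list of allowed values.
#' @export
case_fields <- function() {
  c("case_id", "age", "functional_status", "pt_stage", "pn_stage",
    "nodes_examined", "differentiation", "vascular_invasion",
    "obstruction_or_perforation", "msi_status", "oxaliplatin_contraindicated",
    "serious_liver_disease", "serious_kidney_disease", "resection_margin",
    "perineural_invasion")
}

#' @rdname case_fields
#' @export
field_domains <- function() {
  list(
    age = NULL,                      # integer years, > 0
    functional_status = NULL,        # ECOG 0..5
    pt_stage = c("T1", "T2", "T3", "T4"),
    pn_stage = c("N0", "N1", "N2"),
    nodes_examined = c("LT10", "GE10"),
    differentiation = c("WELL_MODERATE", "POOR_UNDIFF"),
    vascular_invasion = c(FALSE, TRUE),
    obstruction_or_perforation = c(FALSE, TRUE),
    msi_status = c("MSS", "MSI"),
    oxaliplatin_contraindicated = c(FALSE, TRUE),
    serious_liver_disease = c(FALSE, TRUE),
    serious_kidney_disease = c(FALSE, TRUE),
    resection_margin = c("NEGATIVE", "POSITIVE"),
    perineural_invasion = c(FALSE, TRUE)
  )
}

logical_fields <- function() {
  doms <- field_domains()
  names(doms)[vapply(doms, is.logical, logical(1))]
}

#' Validate a set of patient cases
#'
#' Checks column presence, enum membership, logical typing, positive age,
#' ECOG range 0..5, absence of missing values and uniqueness of `case_id`.
#'
#' @param cases A data.frame of cases (one row each).
#' @return The cases, invisibly; errors with a diagnostic on the first
#'   violated invariant.
#' @export
validate_cases <- function(cases) {
  if (!is.data.frame(cases)) stop("cases must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(case_fields(), names(cases))
  if (length(missing_cols)) {
    stop("cases missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cases) == 0L) return(invisible(cases))
  if (anyNA(cases[case_fields()])) stop("cases contain missing values", call. = FALSE)
  if (anyDuplicated(cases$case_id)) stop("case_id values must be unique", call. = FALSE)
  if (!is.numeric(cases$age) || any(cases$age <= 0)) {
    stop("age must be numeric and > 0", call. = FALSE)
  }
  if (!is.numeric(cases$functional_status) ||
      any(!cases$functional_status %in% 0:5)) {
    stop("functional_status must be an ECOG grade in 0..5", call. = FALSE)
  }
  doms <- field_domains()
  for (f in names(doms)) {
    dom <- doms[[f]]
    if (is.null(dom)) next
    v <- cases[[f]]
    if (is.logical(dom)) {
      if (!is.logical(v)) stop(sprintf("field '%s' must be logical", f), call. = FALSE)
    } else if (!all(v %in% dom)) {
      bad <- unique(v[!v %in% dom])
      stop(sprintf("field '%s' has values outside its domain: %s",
                   f, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(cases)
}

# Coerce a single case (one-row data.frame or named list) to a named list.
as_case <- function(case) {
  if (is.data.frame(case)) {
    if (nrow(case) != 1L) stop("expected exactly one case", call. = FALSE)
    case <- as.list(case)
  }
  if (!is.list(case) || is.null(case$case_id)) {
    stop("a case must be a named list or one-row data.frame with case_id",
         call. = FALSE)
  }
  case
}

#' Read / write patient cases as CSV
#'
#' One row per case, one column per field, header row required. Logical
#' fields are serialized as `TRUE`/`FALSE`.
#'
#' @param path File path.
#' @param cases A validated case data.frame.
#' @return `read_cases()` returns the validated case data.frame;
#'   `write_cases()` returns `path` invisibly.
#' @export
read_cases <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  for (f in logical_fields()) {
    if (f %in% names(df)) df[[f]] <- as.logical(df[[f]])
  }
  df <- df[, case_fields(), drop = FALSE]
  validate_cases(df)
  df
}

#' @rdname read_cases
#' @export
write_cases <- function(cases, path) {
  validate_cases(cases)
  utils::write.csv(cases[, case_fields(), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
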