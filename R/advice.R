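#' Advice categories
#'
#' An advice source assigns each catalogue option one of three categories:
#' recommended (`R`), for consideration (`C`) or not recommended (`NR`).
#'
#' @return Character vector `c("R", "C", "NR")`.
#' @export
advice_categories <- function() c("R", "C", "NR")

#' Construct a treatment advice
#'
#' A treatment advice is a total mapping from every catalogue option code to
#' an advice category. Options absent from `categories` are coerced to `NR`
#' so every advice is total over the active catalogue (summation to a fixed
#' score range requires totality).
#'
#' @param categories Named character vector mapping option codes to
#'   categories in `R`/`C`/`NR`. May be partial; missing options become `NR`.
#' @param source `"GUIDELINE"` or `"ADVISOR"`.
#' @param catalogue Treatment catalogue data.frame.
#' @return An object of class `treatment_advice`: a named character vector
#'   over the catalogue codes (in catalogue order) with attribute `source`.
#' @examples
#' treatment_advice(c(OBSERVATION = "R"), source = "GUIDELINE")
#' @export
treatment_advice <- function(categories, source = c("GUIDELINE", "ADVISOR"),
                             catalogue = default_catalogue()) {
  source <- match.arg(source)
  validate_catalogue(catalogue)
  if (length(categories) && is.null(names(categories))) {
    stop("categories must be named by option code", call. = FALSE)
  }
  unknown <- setdiff(names(categories), catalogue$code)
  if (length(unknown)) {
    stop("unknown option codes in advice: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(unname(categories)), advice_categories())
  if (length(bad)) {
    stop("invalid advice categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(rep("NR", nrow(catalogue)), catalogue$code)
  full[names(categories)] <- unname(categories)
  structure(full, source = source, class = "treatment_advice")
}

#' @export
print.treatment_advice <- function(x, ...) {
  cat(sprintf("<treatment_advice source=%s>\n", attr(x, "source")))
  print(stats::setNames(as.character(x), names(x)))
  invisible(x)
}

is_total_advice <- function(advice, catalogue) {
  inherits(advice, "treatment_advice") &&
    identical(names(advice), catalogue$code) &&
    all(advice %in% advice_categories())
}

assert_total_advice <- function(advice, catalogue, what = "advice") {
  if (!is_total_advice(advice, catalogue)) {
    stop(sprintf("%s is not total over the active catalogue", what),
         call. = FALSE)
  }
  invisible(advice)
}
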