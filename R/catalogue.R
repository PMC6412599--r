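#' Default treatment catalogue for the adjuvant colon-cancer setting
#'
#' The catalogue enumerates every treatment option an advice source may be
#' asked about. The default has exactly six options -- observation plus five
#' systemic regimens -- which pins the overall concordance score range to
#' -12..+12 at +/-2 per option.
#'
#' @return A data.frame with columns `code` (unique identifier), `label`
#'   (display string) and `is_chemotherapy` (logical; `FALSE` only for
#'   observation).
#' @examples
#' default_catalogue()
#' @export
default_catalogue <- function() {
  data.frame(
    code = c("OBSERVATION", "CAPE_MONO", "FU_LV_MONO", "CAPOX", "FOLFOX",
             "OTHER_SYSTEMIC"),
    label = c("Observation (no adjuvant therapy)",
              "Capecitabine monotherapy",
              "5-FU/leucovorin monotherapy",
              "CAPOX (capecitabine + oxaliplatin)",
              "FOLFOX (5-FU/leucovorin + oxaliplatin)",
              "Other systemic regimen"),
    is_chemotherapy = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Validate a treatment catalogue
#'
#' @param catalogue A data.frame as returned by [default_catalogue()].
#' @return The catalogue, invisibly; errors on a malformed catalogue.
#' @export
validate_catalogue <- function(catalogue) {
  if (!is.data.frame(catalogue) ||
      !all(c("code", "label", "is_chemotherapy") %in% names(catalogue))) {
    stop("catalogue must be a data.frame with columns code, label, is_chemotherapy",
         call. = FALSE)
  }
  if (nrow(catalogue) < 1L) stop("catalogue must have at least one option", call. = FALSE)
  if (anyDuplicated(catalogue$code)) {
    stop("catalogue option codes must be unique", call. = FALSE)
  }
  if (!is.logical(catalogue$is_chemotherapy) || anyNA(catalogue$is_chemotherapy)) {
    stop("catalogue is_chemotherapy must be logical without NA", call. = FALSE)
  }
  invisible(catalogue)
}

#' Read / write a treatment catalogue as JSON
#'
#' @param path File path.
#' @param catalogue A catalogue data.frame.
#' @return `read_catalogue()` returns the catalogue; `write_catalogue()`
#'   returns `path` invisibly.
#' @export
read_catalogue <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cat <- data.frame(code = as.character(x$code),
                    label = as.character(x$label),
                    is_chemotherapy = as.logical(x$is_chemotherapy),
                    stringsAsFactors = FALSE)
  validate_catalogue(cat)
  cat
}

#' @rdname read_catalogue
#' @export
write_catalogue <- function(catalogue, path) {
  validate_catalogue(catalogue)
  jsonlite::write_json(catalogue, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
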