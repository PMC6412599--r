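#' Cross-tabulation score matrix
#'
#' A score matrix assigns an integer concordance score in -2..+2 to every
#' (guideline category, advisor category) pair. Agreement (the diagonal)
#' scores +2; the extreme disagreements R-vs-NR in either direction score
#' -2. Summing per-option scores over a 6-option catalogue gives the
#' overall case range -12..+12.
#'
#' @param cells 3x3 integer matrix with dimnames `guideline` and `advisor`,
#'   both `R`/`C`/`NR`.
#' @return An object of class `score_matrix` (an integer matrix).
#' @export
score_matrix <- function(cells) {
  cats <- advice_categories()
  if (!is.matrix(cells) || !identical(dim(cells), c(3L, 3L)) ||
      !identical(rownames(cells), cats) || !identical(colnames(cells), cats)) {
    stop("cells must be a 3x3 matrix with R/C/NR row and column names",
         call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  if (any(cells < -2L) || any(cells > 2L)) {
    stop("score matrix cells must lie in [-2, 2]", call. = FALSE)
  }
  if (any(diag(cells) != 2L)) {
    stop("diagonal (agreement) cells must equal +2", call. = FALSE)
  }
  if (cells["R", "NR"] != -2L || cells["NR", "R"] != -2L) {
    stop("cells (R,NR) and (NR,R) must equal -2", call. = FALSE)
  }
  names(dimnames(cells)) <- c("guideline", "advisor")
  structure(cells, class = c("score_matrix", class(cells)))
}

#' Default score matrix
#'
#' Agreement +2; one-step disagreements involving `C` score +1 when the
#' advisor is more conservative or the guideline allows consideration
#' ((R,C) and (C,R)), -1 when consideration meets a prohibition ((C,NR) and
#' (NR,C)); full reversals (R,NR)/(NR,R) score -2. Suggesting a
#' contraindicated treatment for consideration is a less serious error than
#' recommending it outright, hence -1 vs -2. Alternative published matrices
#' can be swapped in via [read_score_matrix()].
#'
#' @return A `score_matrix`.
#' @examples
#' default_matrix()["NR", "R"]  # -2: advisor recommends what is not indicated
#' @export
default_matrix <- function() {
  cats <- advice_categories()
  m <- matrix(c( 2L,  1L, -2L,
                 1L,  2L, -1L,
                -2L, -1L,  2L),
              nrow = 3L, byrow = TRUE,
              dimnames = list(guideline = cats, advisor = cats))
  score_matrix(m)
}

#' Read / write a score matrix as JSON
#'
#' The file is a 3x3 nested object: outer keys are the guideline category,
#' inner keys the advisor category.
#'
#' @param path File path.
#' @param matrix A `score_matrix`.
#' @return `read_score_matrix()` returns the matrix; `write_score_matrix()`
#'   returns `path` invisibly.
#' @export
read_score_matrix <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cats <- advice_categories()
  m <- matrix(NA_integer_, 3L, 3L, dimnames = list(guideline = cats, advisor = cats))
  for (g in cats) for (a in cats) m[g, a] <- as.integer(x[[g]][[a]])
  score_matrix(m)
}

#' @rdname read_score_matrix
#' @export
write_score_matrix <- function(matrix, path) {
  cats <- advice_categories()
  payload <- lapply(stats::setNames(cats, cats), function(g)
    as.list(stats::setNames(as.integer(matrix[g, ]), cats)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Score one case: guideline vs advisor advice
#'
#' Looks up the matrix cell for each catalogue option and sums to the
#' overall concordance score.
#'
#' @param guideline,advisor Total [treatment_advice()] objects over
#'   `catalogue`.
#' @param matrix A `score_matrix`.
#' @param catalogue Treatment catalogue.
#' @return A list with `per_option_scores` (named integer vector in
#'   catalogue order) and `overall_score`.
#' @export
score_case <- function(guideline, advisor, matrix = default_matrix(),
                       catalogue = default_catalogue()) {
  assert_total_advice(guideline, catalogue, "guideline advice")
  assert_total_advice(advisor, catalogue, "advisor advice")
  per <- matrix[cbind(as.character(guideline), as.character(advisor))]
  per <- stats::setNames(as.integer(per), catalogue$code)
  list(per_option_scores = per, overall_score = sum(per))
}

#' Assign a safety flag to a case
#'
#' A case is flagged `RED` when the advisor recommends (`R`) a chemotherapy
#' option the guideline marks not recommended, `ORANGE` when the advisor
#' suggests such an option for consideration (`C`), and `NONE` otherwise.
#' Red takes precedence when both conditions hold. Observation is exempt:
#' flags concern chemotherapy that is not indicated.
#'
#' @inheritParams score_case
#' @return `"RED"`, `"ORANGE"` or `"NONE"`.
#' @export
assign_flag <- function(guideline, advisor, catalogue = default_catalogue()) {
  assert_total_advice(guideline, catalogue, "guideline advice")
  assert_total_advice(advisor, catalogue, "advisor advice")
  chemo <- catalogue$is_chemotherapy[match(names(guideline), catalogue$code)]
  prohibited <- chemo & guideline == "NR"
  if (any(prohibited & advisor == "R")) return("RED")
  if (any(prohibited & advisor == "C")) return("ORANGE")
  "NONE"
}

#' Aggregate case results
#'
#' Summarizes a results table: score minimum, maximum and median (even
#' counts use the lower middle value; the convention is recorded in the
#' output), a score histogram per tumor stage, and flag counts with
#' percentages of the total rounded to the nearest integer percent.
#'
#' @param results A data.frame with columns `case_id`, `stage`,
#'   `overall_score`, `flag` (one row per case), as produced by
#'   [run_evaluation()].
#' @return A list: `n`, `score_min`, `score_max`, `score_median`,
#'   `median_convention`, `histogram_by_stage` (per stage, a named count
#'   vector over observed scores), `flag_counts` and `flag_percent` (named
#'   over `RED`, `ORANGE`, `NONE`).
#' @export
aggregate_results <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("case_id", "stage", "overall_score", "flag") %in% names(results)))
  n <- nrow(results)
  flags <- factor(results$flag, levels = c("RED", "ORANGE", "NONE"))
  counts <- stats::setNames(as.integer(table(flags)), levels(flags))
  pct <- if (n > 0L) round(100 * counts / n) else counts * NA_real_
  hist_by_stage <- lapply(stats::setNames(c("I", "II", "III"), c("I", "II", "III")),
                          function(s) {
                            x <- results$overall_score[results$stage == s]
                            tab <- table(x)
                            stats::setNames(as.integer(tab), names(tab))
                          })
  list(
    n = n,
    score_min = if (n) min(results$overall_score) else NA_integer_,
    score_max = if (n) max(results$overall_score) else NA_integer_,
    score_median = median_lower(results$overall_score),
    median_convention = "lower middle value for even counts",
    histogram_by_stage = hist_by_stage,
    flag_counts = counts,
    flag_percent = stats::setNames(as.numeric(pct), names(counts))
  )
}

# Median taking the lower of the two middle values for even counts.
median_lower <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_integer_)
  sort(x)[ceiling(n / 2)]
}
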