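#' Run the full audit pipeline
#'
#' Enumerates cases from the plan, obtains guideline advice (via the
#' ruleset) and advisor advice (via any [advise()]-capable advisor) per
#' case, scores and flags every case, and writes the results bundle to
#' `out_dir`:
#' \describe{
#'   \item{cases.csv}{the enumerated cases}
#'   \item{guideline_advice.csv / advisor_advice.csv}{long advice tables
#'     (`case_id`, `option_code`, `category`)}
#'   \item{results.csv}{per case: stage, one score column per option,
#'     `overall_score`, `flag`}
#'   \item{case_tables.csv}{stacked per-case analysis tables (one row per
#'     option per case: option label, guideline and advisor categories,
#'     score, free-text comment)}
#'   \item{summary.json}{aggregate of [aggregate_results()] plus per-stage
#'     case counts}
#' }
#' Output is deterministic for a fixed plan, ruleset, advisor and seed.
#'
#' @param plan An `enumeration_plan` (or path to a plan JSON).
#' @param ruleset A `guideline_ruleset` (or path to a ruleset JSON);
#'   defaults to the packaged Dutch tree.
#' @param advisor An advisor object; defaults to the identity mock advisor
#'   backed by `ruleset`.
#' @param matrix A `score_matrix` (or path to a matrix JSON).
#' @param catalogue Treatment catalogue (or path to a catalogue JSON).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @return Invisibly, a list with `cases`, `guideline_advice`,
#'   `advisor_advice` (long data.frames), `results` (the results table) and
#'   `summary`.
#' @export
run_evaluation <- function(plan = default_plan(), ruleset = dutch_tree(),
                           advisor = NULL, matrix = default_matrix(),
                           catalogue = default_catalogue(), out_dir = NULL) {
  if (is.character(plan)) plan <- read_plan(plan)
  if (is.character(ruleset)) ruleset <- read_ruleset(ruleset)
  if (is.character(matrix)) matrix <- read_score_matrix(matrix)
  if (is.character(catalogue)) catalogue <- read_catalogue(catalogue)
  defects <- validate_ruleset(ruleset, catalogue)
  if (nrow(defects)) {
    stop("guideline ruleset has defects:\n",
         paste(sprintf("  [%s] %s: %s", defects$type, defects$node, defects$detail),
               collapse = "\n"), call. = FALSE)
  }
  if (is.null(advisor)) advisor <- ruleset_advisor(ruleset, NULL, catalogue)

  cases <- enumerate_cases(plan, ruleset, catalogue)
  n <- nrow(cases)
  k <- nrow(catalogue)

  g_list <- vector("list", n)
  a_list <- vector("list", n)
  per_scores <- matrix(NA_integer_, n, k, dimnames = list(NULL, catalogue$code))
  flags <- character(n)
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    case <- cases[i, , drop = FALSE]
    g <- evaluate_ruleset(ruleset, case, catalogue)
    a <- advise(advisor, case)
    sc <- score_case(g, a, matrix, catalogue)
    g_list[[i]] <- g
    a_list[[i]] <- a
    per_scores[i, ] <- sc$per_option_scores
    flags[i] <- assign_flag(g, a, catalogue)
    tab <- render_case_table(case, g, a, sc$per_option_scores, catalogue)
    tables[[i]] <- cbind(case_id = case$case_id, tab,
                         stringsAsFactors = FALSE)
  }
  results <- data.frame(case_id = cases$case_id,
                        stage = derive_stage(cases),
                        stringsAsFactors = FALSE)
  score_cols <- paste0(tolower(catalogue$code), "_score")
  for (j in seq_len(k)) results[[score_cols[j]]] <- per_scores[, j]
  results$overall_score <- as.integer(rowSums(per_scores))
  results$flag <- flags

  summary <- aggregate_results(results)
  summary$cases_by_stage <- as.list(count_by_stage(cases))

  bundle <- list(cases = cases,
                 guideline_advice = advice_long(cases$case_id, g_list),
                 advisor_advice = advice_long(cases$case_id, a_list),
                 results = results,
                 case_tables = do.call(rbind, tables),
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cases(cases, file.path(out_dir, "cases.csv"))
    utils::write.csv(bundle$guideline_advice,
                     file.path(out_dir, "guideline_advice.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(bundle$advisor_advice,
                     file.path(out_dir, "advisor_advice.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(bundle$case_tables, file.path(out_dir, "case_tables.csv"),
                     row.names = FALSE)
    write_summary(summary, file.path(out_dir, "summary.json"))
  }
  invisible(bundle)
}

advice_long <- function(case_ids, advice_list) {
  k <- length(advice_list[[1]])
  data.frame(
    case_id = rep(case_ids, each = k),
    option_code = unlist(lapply(advice_list, names), use.names = FALSE),
    category = unlist(lapply(advice_list, as.character), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

write_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Render the per-case analysis table
#'
#' One row per catalogue option, in catalogue order: option label, the
#' guideline and advisor categories verbatim (`R`/`C`/`NR`), the per-option
#' score, and a free-text comment column (empty by default).
#'
#' @param case A single patient case.
#' @param guideline,advisor Total [treatment_advice()] objects.
#' @param scores Named per-option integer scores (as from [score_case()]).
#' @param catalogue Treatment catalogue.
#' @return A data.frame with columns `option`, `guideline`, `advisor`,
#'   `score`, `comment` and exactly `nrow(catalogue)` rows.
#' @export
render_case_table <- function(case, guideline, advisor, scores,
                              catalogue = default_catalogue()) {
  assert_total_advice(guideline, catalogue, "guideline advice")
  assert_total_advice(advisor, catalogue, "advisor advice")
  data.frame(option = catalogue$label,
             guideline = as.character(guideline[catalogue$code]),
             advisor = as.character(advisor[catalogue$code]),
             score = as.integer(scores[catalogue$code]),
             comment = "",
             stringsAsFactors = FALSE)
}
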