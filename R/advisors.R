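#' Perturbation configuration for the mock advisor
#'
#' Describes how the mock advisor's output deviates from its backing
#' ruleset: for each ordered category pair, the probability that an option
#' whose backing category is `from` is shifted to `to`. Residual mass means
#' no change. Each option is perturbed independently, using a random stream
#' derived from `(seed, case_id, option code)` so outcomes are reproducible
#' and independent of case order.
#'
#' @param shift_probabilities Named numeric vector; names are ordered pairs
#'   `"R->C"`, `"R->NR"`, `"C->R"`, `"C->NR"`, `"NR->R"`, `"NR->C"`.
#' @param seed Integer base seed.
#' @return An object of class `perturbation_config`.
#' @examples
#' perturbation_config(c("R->C" = 0.3), seed = 7)
#' @export
perturbation_config <- function(shift_probabilities = numeric(0), seed = 0L) {
  cats <- advice_categories()
  valid_pairs <- as.vector(outer(cats, cats, function(a, b) paste0(a, "->", b)))
  valid_pairs <- valid_pairs[rep(cats, times = length(cats)) !=
                               rep(cats, each = length(cats))]
  if (length(shift_probabilities)) {
    if (is.null(names(shift_probabilities)) ||
        !all(names(shift_probabilities) %in% valid_pairs)) {
      stop("shift probabilities must be named by ordered pairs like 'R->C'",
           call. = FALSE)
    }
    if (any(shift_probabilities < 0 | shift_probabilities > 1)) {
      stop("shift probabilities must lie in [0, 1]", call. = FALSE)
    }
    from <- sub("->.*$", "", names(shift_probabilities))
    sums <- tapply(shift_probabilities, from, sum)
    if (any(sums > 1 + 1e-12)) {
      stop("outgoing shift probabilities must sum to <= 1 per source category",
           call. = FALSE)
    }
  }
  structure(list(shift_probabilities = shift_probabilities,
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

# 32-bit FNV-1a hash of a string, folded into a valid set.seed() integer.
fnv_hash <- function(key) {
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

# Draw one uniform from a stream keyed by an arbitrary string, leaving the
# caller's RNG state untouched.
hashed_runif <- function(key) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(fnv_hash(key))
  stats::runif(1L)
}

#' Advisor constructors
#'
#' An advisor is any object with an [advise()] method returning a total
#' [treatment_advice()] with `source = "ADVISOR"` for a case.
#'
#' `ruleset_advisor()` backs the advisor by a declarative ruleset,
#' optionally perturbed per [perturbation_config()] -- a stand-in for a
#' proprietary black box whose behavior can be made deliberately
#' discordant for testing. `recorded_advisor()` replays externally captured
#' advice from a [recorded store][load_recorded()].
#'
#' @param ruleset A `guideline_ruleset`.
#' @param perturbation A `perturbation_config`, or `NULL` for the identity
#'   advisor.
#' @param store A `recorded_advice_store`.
#' @param catalogue Treatment catalogue.
#' @return An advisor object.
#' @export
ruleset_advisor <- function(ruleset, perturbation = NULL,
                            catalogue = default_catalogue()) {
  if (!is.null(perturbation) && !inherits(perturbation, "perturbation_config")) {
    stop("perturbation must be a perturbation_config or NULL", call. = FALSE)
  }
  structure(list(ruleset = ruleset, perturbation = perturbation,
                 catalogue = catalogue),
            class = c("ruleset_advisor", "advisor"))
}

#' @rdname ruleset_advisor
#' @export
recorded_advisor <- function(store, catalogue = default_catalogue()) {
  if (!inherits(store, "recorded_advice_store")) {
    stop("store must be a recorded_advice_store", call. = FALSE)
  }
  structure(list(store = store, catalogue = catalogue),
            class = c("recorded_advisor", "advisor"))
}

#' Obtain advisor advice for a case
#'
#' @param advisor An advisor object.
#' @param case A single patient case.
#' @param ... Passed to methods.
#' @return A total [treatment_advice()] with `source = "ADVISOR"`.
#' @export
advise <- function(advisor, case, ...) UseMethod("advise")

#' @export
advise.ruleset_advisor <- function(advisor, case, ...) {
  case <- as_case(case)
  advice <- evaluate_ruleset(advisor$ruleset, case, advisor$catalogue,
                             source = "ADVISOR")
  cfg <- advisor$perturbation
  if (is.null(cfg) || !length(cfg$shift_probabilities)) return(advice)
  probs <- cfg$shift_probabilities
  from_all <- sub("->.*$", "", names(probs))
  to_all <- sub("^.*->", "", names(probs))
  cats <- advice_categories()
  out <- unclass(advice)
  for (code in names(out)) {
    from <- out[[code]]
    idx <- which(from_all == from)
    if (!length(idx)) next
    idx <- idx[order(match(to_all[idx], cats))] # deterministic target order
    u <- hashed_runif(paste(cfg$seed, case$case_id, code, sep = "\r"))
    cum <- cumsum(probs[idx])
    hit <- which(u < cum)
    if (length(hit)) out[[code]] <- to_all[idx[hit[1L]]]
  }
  treatment_advice(out, source = "ADVISOR", catalogue = advisor$catalogue)
}

#' @export
advise.recorded_advisor <- function(advisor, case, ...) {
  case <- as_case(case)
  advice <- advisor$store$entries[[case$case_id]]
  if (is.null(advice)) {
    stop(structure(
      class = c("cdssaudit_missing_advice", "error", "condition"),
      list(message = sprintf("no recorded advice for case '%s'", case$case_id),
           call = NULL)))
  }
  advice
}

#' Mock advice in one call
#'
#' Convenience wrapper: evaluates `ruleset` on `case` and applies the
#' perturbation, equivalent to `advise(ruleset_advisor(ruleset, config), case)`.
#'
#' @inheritParams ruleset_advisor
#' @param config A `perturbation_config`.
#' @param case A single patient case.
#' @return A total [treatment_advice()] with `source = "ADVISOR"`.
#' @export
mock_advise <- function(ruleset, config, case, catalogue = default_catalogue()) {
  advise(ruleset_advisor(ruleset, config, catalogue), case)
}

# ---- recorded advice stores -------------------------------------------------

#' Construct a recorded-advice store
#'
#' @param entries Named list mapping `case_id` to [treatment_advice()].
#' @return An object of class `recorded_advice_store`.
#' @export
recorded_advice_store <- function(entries = list()) {
  if (length(entries) && (is.null(names(entries)) || anyDuplicated(names(entries)))) {
    stop("store entries must be uniquely named by case_id", call. = FALSE)
  }
  structure(list(entries = entries), class = "recorded_advice_store")
}

#' @export
print.recorded_advice_store <- function(x, ...) {
  cat(sprintf("<recorded_advice_store: %d cases>\n", length(x$entries)))
  invisible(x)
}

#' @export
length.recorded_advice_store <- function(x) length(x$entries)

#' Load / save recorded advisor advice
#'
#' The on-disk dialect is a long CSV with columns `case_id`, `option_code`,
#' `category` (one of `R`, `C`, `NR`); a JSON equivalent
#' (`{case_id: {option_code: category, ...}, ...}`) is selected by a
#' `.json` extension. Absent (case, option) pairs are coerced to `NR` on
#' load, so every stored advice is total over the catalogue. `save_recorded()`
#' writes a normalized file (cases sorted by id, options in catalogue
#' order), so save-then-load round-trips byte-identically.
#'
#' @param path File path (`.csv` or `.json`).
#' @param store A `recorded_advice_store`.
#' @param catalogue Treatment catalogue.
#' @return `load_recorded()` returns the store; `save_recorded()` returns
#'   `path` invisibly.
#' @export
load_recorded <- function(path, catalogue = default_catalogue()) {
  validate_catalogue(catalogue)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    if (length(x) && anyDuplicated(names(x))) {
      stop("duplicate case_id in recorded advice", call. = FALSE)
    }
    entries <- lapply(x, function(adv)
      treatment_advice(unlist(adv), source = "ADVISOR", catalogue = catalogue))
    return(recorded_advice_store(entries))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("case_id", "option_code", "category")
  if (!all(needed %in% names(df))) {
    stop("recorded advice CSV must have columns case_id, option_code, category",
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(recorded_advice_store())
  unknown <- setdiff(unique(df$option_code), catalogue$code)
  if (length(unknown)) {
    stop("unknown option codes in recorded advice: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("case_id", "option_code")])) {
    stop("duplicate (case_id, option_code) in recorded advice", call. = FALSE)
  }
  entries <- lapply(split(df, df$case_id), function(d)
    treatment_advice(stats::setNames(d$category, d$option_code),
                     source = "ADVISOR", catalogue = catalogue))
  recorded_advice_store(entries)
}

#' @rdname load_recorded
#' @export
save_recorded <- function(store, path, catalogue = default_catalogue()) {
  if (!inherits(store, "recorded_advice_store")) {
    stop("store must be a recorded_advice_store", call. = FALSE)
  }
  ids <- sort(names(store$entries))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- lapply(stats::setNames(ids, ids), function(id)
      as.list(stats::setNames(as.character(store$entries[[id]]),
                              names(store$entries[[id]]))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  rows <- lapply(ids, function(id) {
    adv <- store$entries[[id]]
    data.frame(case_id = id, option_code = names(adv),
               category = as.character(adv), stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), option_code = character(0),
               category = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
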