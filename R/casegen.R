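#' Decision-point specification
#'
#' A decision point is any patient, clinical or tumor characteristic whose
#' value can change a recommendation. A point is either tested over a list
#' of values (for continuous variables, a purposive sample) or held constant
#' at a single value.
#'
#' @param name A patient-case field name (see [case_fields()]).
#' @param values Ordered vector of tested values; required unless
#'   `constant` is given.
#' @param constant Single value at which the point is held; mutually
#'   exclusive with `values`.
#' @return A list with fields `name`, `kind` (`"CATEGORICAL"` or
#'   `"CONTINUOUS"`), `tested_values`, `held_constant`, `constant_value`.
#' @export
decision_point <- function(name, values = NULL, constant = NULL) {
  doms <- field_domains()
  if (!name %in% names(doms)) {
    stop(sprintf("'%s' is not a patient-case field", name), call. = FALSE)
  }
  held <- !is.null(constant)
  if (held == !is.null(values)) {
    stop(sprintf("point '%s': give exactly one of values= or constant=", name),
         call. = FALSE)
  }
  if (held && length(constant) != 1L) {
    stop(sprintf("point '%s': constant must be a single value", name),
         call. = FALSE)
  }
  dom <- doms[[name]]
  tested <- if (held) NULL else values
  if (!is.null(dom)) {
    vals <- if (held) constant else values
    if (!all(norm_value(vals) %in% norm_value(dom))) {
      stop(sprintf("point '%s': values outside the field domain", name),
           call. = FALSE)
    }
  }
  list(name = name,
       kind = if (is.null(dom)) "CONTINUOUS" else "CATEGORICAL",
       tested_values = tested,
       held_constant = held,
       constant_value = if (held) constant else NULL)
}

#' Enumeration plan over decision points
#'
#' A plan lists one [decision_point()] per patient-case field, the
#' enumeration mode, and the attribution of point names to the guideline's
#' decision-point set and the advisor's minimum variable set.
#'
#' @param points List of decision points covering every case field exactly
#'   once (all fields except `case_id`).
#' @param mode `"FULL_FACTORIAL"` (Cartesian product of tested values) or
#'   `"PATH_DEDUP"` (one representative per (guideline advice, stage)
#'   signature).
#' @param guideline_point_names,advisor_point_names Character subsets of the
#'   point names.
#' @return An object of class `enumeration_plan`.
#' @export
enumeration_plan <- function(points, mode = c("FULL_FACTORIAL", "PATH_DEDUP"),
                             guideline_point_names = character(0),
                             advisor_point_names = character(0)) {
  mode <- match.arg(mode)
  nm <- vapply(points, `[[`, character(1), "name")
  expected <- setdiff(case_fields(), "case_id")
  if (anyDuplicated(nm) || !setequal(nm, expected)) {
    stop("plan points must cover every patient-case field exactly once",
         call. = FALSE)
  }
  for (set in list(guideline_point_names, advisor_point_names)) {
    if (!all(set %in% nm)) {
      stop("attributed point names must be a subset of the plan's point names",
           call. = FALSE)
    }
  }
  structure(list(points = stats::setNames(points, nm), mode = mode,
                 guideline_point_names = guideline_point_names,
                 advisor_point_names = advisor_point_names),
            class = "enumeration_plan")
}

#' @export
print.enumeration_plan <- function(x, ...) {
  tested <- !vapply(x$points, `[[`, logical(1), "held_constant")
  cat(sprintf("<enumeration_plan: %d points (%d tested, %d constant), mode %s>\n",
              length(x$points), sum(tested), sum(!tested), x$mode))
  invisible(x)
}

#' Default enumeration plan
#'
#' The packaged plan behind the feasibility audit of the Dutch adjuvant
#' colon-cancer guideline. Tested points: age at three purposive levels
#' (45, 60, 75 years -- young, average, older), pT stage (4), pN stage (3),
#' and eight binary points (nodes examined, differentiation, vascular
#' invasion, obstruction/perforation, MSI status, oxaliplatin
#' contraindication, serious liver disease, serious kidney disease). Held
#' constant at normal/absent: resection margin negative, perineural
#' invasion absent, functional status ECOG 0.
#'
#' The guideline attribution has 9 points and the advisor (minimum variable)
#' attribution 13; they share 8, for 14 unique decision points, with
#' oxaliplatin contraindication the one guideline-only point and the 5
#' advisor-only points being the two comorbidity variables plus the three
#' held-constant ones.
#'
#' @param mode Enumeration mode, `"FULL_FACTORIAL"` by default.
#' @return An `enumeration_plan`.
#' @export
default_plan <- function(mode = "FULL_FACTORIAL") {
  points <- list(
    decision_point("age", values = c(45L, 60L, 75L)),
    decision_point("pt_stage", values = c("T1", "T2", "T3", "T4")),
    decision_point("pn_stage", values = c("N0", "N1", "N2")),
    decision_point("nodes_examined", values = c("LT10", "GE10")),
    decision_point("differentiation", values = c("WELL_MODERATE", "POOR_UNDIFF")),
    decision_point("vascular_invasion", values = c(FALSE, TRUE)),
    decision_point("obstruction_or_perforation", values = c(FALSE, TRUE)),
    decision_point("msi_status", values = c("MSS", "MSI")),
    decision_point("oxaliplatin_contraindicated", values = c(FALSE, TRUE)),
    decision_point("serious_liver_disease", values = c(FALSE, TRUE)),
    decision_point("serious_kidney_disease", values = c(FALSE, TRUE)),
    decision_point("resection_margin", constant = "NEGATIVE"),
    decision_point("perineural_invasion", constant = FALSE),
    decision_point("functional_status", constant = 0L)
  )
  guideline <- c("age", "pt_stage", "pn_stage", "nodes_examined",
                 "differentiation", "vascular_invasion",
                 "obstruction_or_perforation", "msi_status",
                 "oxaliplatin_contraindicated")
  advisor <- setdiff(vapply(points, `[[`, character(1), "name"),
                     "oxaliplatin_contraindicated")
  enumeration_plan(points, mode = mode,
                   guideline_point_names = guideline,
                   advisor_point_names = advisor)
}

#' Enumerate synthetic patient cases from a plan
#'
#' `FULL_FACTORIAL` yields the Cartesian product of tested values across all
#' non-constant points, constants filled in, in deterministic lexicographic
#' order (the first tested point varies slowest, each point's values in
#' listed order); `case_id` is the zero-padded ordinal. `PATH_DEDUP` reduces
#' that set to one representative per distinct (guideline advice, stage)
#' signature, keeping the lexicographically first member with its original
#' `case_id`.
#'
#' @param plan An `enumeration_plan`.
#' @param ruleset Ruleset used to compute advice signatures in `PATH_DEDUP`
#'   mode (default: the packaged Dutch tree).
#' @param catalogue Treatment catalogue.
#' @return A validated case data.frame.
#' @export
enumerate_cases <- function(plan, ruleset = dutch_tree(),
                            catalogue = default_catalogue()) {
  if (!inherits(plan, "enumeration_plan")) {
    stop("plan must be an enumeration_plan", call. = FALSE)
  }
  tested <- Filter(function(p) !p$held_constant, plan$points)
  constants <- Filter(function(p) p$held_constant, plan$points)
  value_lists <- lapply(tested, `[[`, "tested_values")
  # expand.grid varies the first factor fastest; reverse to get lexicographic
  # order with the first plan point most significant
  grid <- expand.grid(rev(value_lists), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  n <- nrow(grid)
  for (p in constants) grid[[p$name]] <- rep(p$constant_value, n)
  width <- max(4L, nchar(as.character(n)))
  grid$case_id <- sprintf(paste0("%0", width, "d"), seq_len(n))
  cases <- grid[, case_fields(), drop = FALSE]
  rownames(cases) <- NULL
  validate_cases(cases)
  if (plan$mode == "PATH_DEDUP") {
    sig <- advice_signatures(cases, ruleset, catalogue)
    cases <- cases[!duplicated(sig), , drop = FALSE]
    rownames(cases) <- NULL
  }
  cases
}

# One string per case: guideline advice categories in catalogue order,
# joined with the derived stage.
advice_signatures <- function(cases, ruleset, catalogue) {
  stage <- derive_stage(cases)
  adv <- vapply(seq_len(nrow(cases)), function(i) {
    paste(evaluate_ruleset(ruleset, cases[i, , drop = FALSE], catalogue),
          collapse = "|")
  }, character(1))
  paste(adv, stage, sep = "@")
}

#' Count enumerated cases by tumor stage
#'
#' @param cases A case data.frame.
#' @return Named integer vector over stages `I`, `II`, `III` (all present,
#'   zero-filled).
#' @export
count_by_stage <- function(cases) {
  validate_cases(cases)
  stage <- factor(derive_stage(cases), levels = c("I", "II", "III"))
  out <- table(stage)
  stats::setNames(as.integer(out), names(out))
}

# ---- plan file IO -----------------------------------------------------------

#' Read / write an enumeration plan as JSON
#'
#' @param path File path.
#' @param plan An `enumeration_plan`.
#' @return `read_plan()` returns the plan; `write_plan()` returns `path`
#'   invisibly.
#' @export
read_plan <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  points <- lapply(x$points, function(p) {
    vals <- if (is.null(p$values)) NULL else restore_point_values(p$name, unlist(p$values))
    konst <- if (is.null(p$constant)) NULL else restore_point_values(p$name, unlist(p$constant))
    decision_point(p$name, values = vals, constant = konst)
  })
  enumeration_plan(points, mode = x$mode,
                   guideline_point_names = as.character(unlist(x$guideline_point_names)),
                   advisor_point_names = as.character(unlist(x$advisor_point_names)))
}

restore_point_values <- function(name, vals) {
  dom <- field_domains()[[name]]
  if (is.null(dom)) return(as.integer(vals))
  if (is.logical(dom)) return(as.logical(vals))
  as.character(vals)
}

#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  points <- lapply(unname(plan$points), function(p) {
    out <- list(name = p$name)
    if (p$held_constant) out$constant <- p$constant_value
    else out$values <- as.list(p$tested_values)
    out
  })
  jsonlite::write_json(list(points = points, mode = plan$mode,
                            guideline_point_names = as.list(plan$guideline_point_names),
                            advisor_point_names = as.list(plan$advisor_point_names)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load the packaged default plan file
#'
#' @return An `enumeration_plan`, identical to [default_plan()].
#' @export
packaged_plan <- function() {
  read_plan(system.file("extdata", "default_plan.json", package = "cdssaudit",
                        mustWork = TRUE))
}
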