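#' Derive AJCC TNM stage group from pT/pN
#'
#' Node-positive disease (N1/N2) is stage III; node-negative T1/T2 is
#' stage I; node-negative T3/T4 is stage II. Vectorized over a case set.
#'
#' @param case A single case (named list / one-row data.frame) or a case
#'   data.frame.
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @export
derive_stage <- function(case) {
  pt <- if (is.data.frame(case)) case$pt_stage else case$pt_stage
  pn <- if (is.data.frame(case)) case$pn_stage else case$pn_stage
  ifelse(pn %in% c("N1", "N2"), "III",
         ifelse(pt %in% c("T1", "T2"), "I", "II"))
}

#' High-risk features for stage II colon cancer
#'
#' Stage II disease is high-risk when at least one of the following is
#' present: pT4 tumor, fewer than 10 examined regional lymph nodes, poorly
#' or undifferentiated histology, (extramural) vascular invasion, or
#' presentation with obstruction/perforation.
#'
#' @param case A stage-II case (or case data.frame of stage-II cases).
#' @return Logical vector.
#' @export
is_high_risk_stage_ii <- function(case) {
  stage <- derive_stage(case)
  if (any(stage != "II")) {
    stop("is_high_risk_stage_ii() called on a non-stage-II case", call. = FALSE)
  }
  get <- function(f) if (is.data.frame(case)) case[[f]] else case[[f]]
  get("pt_stage") == "T4" |
    get("nodes_examined") == "LT10" |
    get("differentiation") == "POOR_UNDIFF" |
    as.logical(get("vascular_invasion")) |
    as.logical(get("obstruction_or_perforation"))
}

# Canonical leaf advices of the Dutch adjuvant colon-cancer logic.
advice_observation <- function(catalogue, source = "GUIDELINE") {
  treatment_advice(c(OBSERVATION = "R"), source = source, catalogue = catalogue)
}
advice_consider_doublet <- function(catalogue, source = "GUIDELINE") {
  treatment_advice(c(OBSERVATION = "R", CAPOX = "C", FOLFOX = "C"),
                   source = source, catalogue = catalogue)
}
advice_doublet <- function(catalogue, source = "GUIDELINE") {
  treatment_advice(c(CAPOX = "R", FOLFOX = "R"),
                   source = source, catalogue = catalogue)
}
advice_fluoropyrimidine_mono <- function(catalogue, source = "GUIDELINE") {
  treatment_advice(c(CAPE_MONO = "R", FU_LV_MONO = "R"),
                   source = source, catalogue = catalogue)
}

#' Dutch adjuvant colon-cancer guideline advice (hard-coded oracle)
#'
#' Direct encoding of the Dutch guideline logic for adjuvant treatment after
#' resection of stage I-III colon cancer:
#' \itemize{
#'   \item Stage I, and stage II without high-risk features: observation
#'     only; chemotherapy not indicated.
#'   \item High-risk stage II (see [is_high_risk_stage_ii()]): an
#'     oxaliplatin doublet (CAPOX/FOLFOX) may be considered, provided the
#'     tumor is MSS and oxaliplatin is not contraindicated; otherwise
#'     observation.
#'   \item Stage III: an oxaliplatin doublet is the regimen of choice. If
#'     oxaliplatin is contraindicated and the tumor is MSS,
#'     fluoropyrimidine monotherapy; if contraindicated and MSI,
#'     chemotherapy is not indicated (monotherapy confers no benefit in MSI
#'     tumors).
#' }
#' Age and functional status are carried on the case but do not alter the
#' advice, matching the source guideline trees.
#'
#' This oracle exists independently of the declarative tree shipped in
#' `inst/extdata/dutch_adjuvant_colon_ruleset.json`; the test suite proves
#' the two agree on every enumerated case.
#'
#' @param case A single patient case.
#' @param catalogue Treatment catalogue.
#' @return A [treatment_advice()] with `source = "GUIDELINE"`.
#' @export
dutch_advice <- function(case, catalogue = default_catalogue()) {
  case <- as_case(case)
  stage <- derive_stage(case)
  if (stage == "I") return(advice_observation(catalogue))
  if (stage == "II") {
    if (!is_high_risk_stage_ii(case)) return(advice_observation(catalogue))
    if (case$msi_status == "MSI" || isTRUE(as.logical(case$oxaliplatin_contraindicated))) {
      return(advice_observation(catalogue))
    }
    return(advice_consider_doublet(catalogue))
  }
  # stage III
  if (!isTRUE(as.logical(case$oxaliplatin_contraindicated))) {
    return(advice_doublet(catalogue))
  }
  if (case$msi_status == "MSS") return(advice_fluoropyrimidine_mono(catalogue))
  advice_observation(catalogue)
}

# ---- declarative rulesets ---------------------------------------------------

# Edge labels and case values are compared on a normalized string form so
# logical fields serialize naturally in JSON ("TRUE"/"FALSE").
norm_value <- function(x) toupper(as.character(x))

#' Construct a declarative guideline ruleset
#'
#' A ruleset is a rooted acyclic graph of decision nodes and leaves.
#' Decision nodes reference one finite-domain patient-case field and carry
#' outgoing edges labeled by disjoint value sets; leaves carry a treatment
#' advice (possibly partial; coerced total with `NR`).
#'
#' @param name Ruleset name.
#' @param root Identifier of the root node.
#' @param nodes Named list. A decision node is
#'   `list(field = "<case field>", edges = list(list(values = c(...),
#'   target = "<node id>"), ...))`; a leaf is
#'   `list(advice = c(OPTION = "R", ...))`.
#' @return An object of class `guideline_ruleset`.
#' @seealso [validate_ruleset()], [evaluate_ruleset()], [read_ruleset()]
#' @export
guideline_ruleset <- function(name, root, nodes) {
  if (is.null(names(nodes)) || anyDuplicated(names(nodes))) {
    stop("nodes must be a uniquely named list", call. = FALSE)
  }
  structure(list(name = name, root = root, nodes = nodes),
            class = "guideline_ruleset")
}

#' @export
print.guideline_ruleset <- function(x, ...) {
  leaves <- vapply(x$nodes, function(n) !is.null(n$advice), logical(1))
  cat(sprintf("<guideline_ruleset '%s': %d decision nodes, %d leaves, root '%s'>\n",
              x$name, sum(!leaves), sum(leaves), x$root))
  invisible(x)
}

is_leaf_node <- function(node) !is.null(node$advice)

#' Validate a declarative ruleset
#'
#' Checks that the graph is acyclic, every referenced node exists, every
#' path from the root terminates in a leaf, each decision node references a
#' known finite-domain field, and the edge value sets at each node are
#' disjoint (determinism) and cover the field's domain (completeness).
#'
#' Defects are returned, not raised, so a broken ruleset can be reported in
#' full.
#'
#' @param ruleset A `guideline_ruleset`.
#' @param catalogue Treatment catalogue (leaf advices are checked against it).
#' @return A data.frame with columns `node`, `type`, `detail`; zero rows iff
#'   the ruleset is well-formed. Defect types: `missing_root`,
#'   `missing_target`, `cycle`, `unsupported_field`, `unknown_field`,
#'   `overlap`, `gap`, `bad_leaf`, `unreachable`.
#' @export
validate_ruleset <- function(ruleset, catalogue = default_catalogue()) {
  defects <- list()
  add <- function(node, type, detail) {
    defects[[length(defects) + 1L]] <<- data.frame(
      node = node, type = type, detail = detail, stringsAsFactors = FALSE)
  }
  nodes <- ruleset$nodes
  doms <- field_domains()
  if (!ruleset$root %in% names(nodes)) {
    add(ruleset$root, "missing_root", "root node not present")
    return(do.call(rbind, defects))
  }
  for (id in names(nodes)) {
    node <- nodes[[id]]
    if (is_leaf_node(node)) {
      adv <- node$advice
      if (length(adv) == 0L || is.null(names(adv))) {
        add(id, "bad_leaf", "leaf advice must be a named category vector")
        next
      }
      if (!all(unname(unlist(adv)) %in% advice_categories())) {
        add(id, "bad_leaf", "leaf advice has categories outside R/C/NR")
      }
      unknown <- setdiff(names(adv), catalogue$code)
      if (length(unknown)) {
        add(id, "bad_leaf",
            paste("unknown option codes:", paste(unknown, collapse = ", ")))
      }
      next
    }
    f <- node$field
    if (is.null(f) || !f %in% names(doms)) {
      add(id, "unknown_field", paste("unknown case field:", f))
      next
    }
    dom <- doms[[f]]
    if (is.null(dom)) {
      add(id, "unsupported_field",
          paste0("field '", f, "' is continuous; decision nodes require a finite domain"))
      next
    }
    dom <- norm_value(dom)
    labels <- lapply(node$edges, function(e) norm_value(e$values))
    all_labels <- unlist(labels)
    dup <- unique(all_labels[duplicated(all_labels)])
    if (length(dup)) {
      add(id, "overlap",
          paste("values on multiple edges:", paste(dup, collapse = ", ")))
    }
    uncovered <- setdiff(dom, all_labels)
    if (length(uncovered)) {
      add(id, "gap",
          paste("uncovered domain values:", paste(uncovered, collapse = ", ")))
    }
    foreign <- setdiff(all_labels, dom)
    if (length(foreign)) {
      add(id, "gap",
          paste("edge values outside the field domain:",
                paste(foreign, collapse = ", ")))
    }
    for (e in node$edges) {
      if (!e$target %in% names(nodes)) {
        add(id, "missing_target", paste("edge targets unknown node:", e$target))
      }
    }
  }
  # cycle + reachability via iterative DFS from the root
  color <- stats::setNames(rep(0L, length(nodes)), names(nodes)) # 0 new, 1 open, 2 done
  visit <- function(id, path) {
    if (!id %in% names(nodes)) return(invisible())
    if (color[[id]] == 1L) {
      add(id, "cycle", paste("cycle via path:", paste(c(path, id), collapse = " -> ")))
      return(invisible())
    }
    if (color[[id]] == 2L) return(invisible())
    color[[id]] <<- 1L
    node <- nodes[[id]]
    if (!is_leaf_node(node)) {
      for (e in node$edges) visit(e$target, c(path, id))
    }
    color[[id]] <<- 2L
  }
  visit(ruleset$root, character(0))
  unreachable <- names(nodes)[color == 0L]
  for (id in unreachable) add(id, "unreachable", "node not reachable from root")
  out <- if (length(defects)) do.call(rbind, defects) else
    data.frame(node = character(0), type = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate a ruleset on a patient case
#'
#' Follows edges from the root by matching the case's field values until a
#' leaf is reached; returns the leaf's advice, coerced total over the
#' catalogue.
#'
#' @param ruleset A `guideline_ruleset` (validate first; a case value that
#'   matches no edge signals a ruleset defect).
#' @param case A single patient case.
#' @param catalogue Treatment catalogue.
#' @param source Source tag for the returned advice.
#' @return A [treatment_advice()].
#' @export
evaluate_ruleset <- function(ruleset, case, catalogue = default_catalogue(),
                             source = "GUIDELINE") {
  case <- as_case(case)
  id <- ruleset$root
  for (i in seq_len(length(ruleset$nodes) + 1L)) {
    node <- ruleset$nodes[[id]]
    if (is.null(node)) {
      stop(sprintf("ruleset defect: node '%s' does not exist", id), call. = FALSE)
    }
    if (is_leaf_node(node)) {
      return(treatment_advice(unlist(node$advice), source = source,
                              catalogue = catalogue))
    }
    value <- norm_value(case[[node$field]])
    nxt <- NULL
    for (e in node$edges) {
      if (value %in% norm_value(e$values)) { nxt <- e$target; break }
    }
    if (is.null(nxt)) {
      stop(sprintf("ruleset defect: node '%s' has no edge for %s = %s",
                   id, node$field, value), call. = FALSE)
    }
    id <- nxt
  }
  stop("ruleset defect: evaluation did not terminate (cycle?)", call. = FALSE)
}

#' The Dutch adjuvant colon-cancer guideline as a declarative tree
#'
#' Builds the packaged declarative encoding of the same logic as
#' [dutch_advice()]. The test suite verifies node-by-node equivalence of the
#' two routes on every enumerated case.
#'
#' @return A `guideline_ruleset`.
#' @export
dutch_tree <- function() {
  e <- function(values, target) list(values = values, target = target)
  dn <- function(field, ...) list(field = field, edges = list(...))
  leaf <- function(advice) list(advice = advice)
  guideline_ruleset(
    name = "dutch_adjuvant_colon",
    root = "pn",
    nodes = list(
      pn = dn("pn_stage", e("N0", "pt"), e(c("N1", "N2"), "s3_oxa")),
      pt = dn("pt_stage", e(c("T1", "T2"), "leaf_obs"),
              e("T3", "s2_nodes"), e("T4", "s2_msi")),
      # stage II risk cascade: any high-risk feature routes to the MSI gate
      s2_nodes = dn("nodes_examined", e("LT10", "s2_msi"), e("GE10", "s2_diff")),
      s2_diff = dn("differentiation", e("POOR_UNDIFF", "s2_msi"),
                   e("WELL_MODERATE", "s2_vasc")),
      s2_vasc = dn("vascular_invasion", e("TRUE", "s2_msi"),
                   e("FALSE", "s2_obstr")),
      s2_obstr = dn("obstruction_or_perforation", e("TRUE", "s2_msi"),
                    e("FALSE", "leaf_obs")),
      s2_msi = dn("msi_status", e("MSI", "leaf_obs"), e("MSS", "s2_oxa")),
      s2_oxa = dn("oxaliplatin_contraindicated", e("TRUE", "leaf_obs"),
                  e("FALSE", "leaf_consider_doublet")),
      s3_oxa = dn("oxaliplatin_contraindicated", e("FALSE", "leaf_doublet"),
                  e("TRUE", "s3_msi")),
      s3_msi = dn("msi_status", e("MSS", "leaf_mono"), e("MSI", "leaf_obs")),
      leaf_obs = leaf(c(OBSERVATION = "R")),
      leaf_consider_doublet = leaf(c(OBSERVATION = "R", CAPOX = "C", FOLFOX = "C")),
      leaf_doublet = leaf(c(CAPOX = "R", FOLFOX = "R")),
      leaf_mono = leaf(c(CAPE_MONO = "R", FU_LV_MONO = "R"))
    )
  )
}

#' Read / write a ruleset as JSON
#'
#' The file format mirrors the in-memory structure: `name`, `root`, and a
#' `nodes` object whose members are either decision nodes (`field`, `edges`
#' with `values` and `target`) or leaves (`advice` mapping option codes to
#' `"R"|"C"|"NR"`).
#'
#' @param path File path.
#' @param ruleset A `guideline_ruleset`.
#' @return `read_ruleset()` returns the ruleset; `write_ruleset()` returns
#'   `path` invisibly.
#' @export
read_ruleset <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nodes <- lapply(x$nodes, function(n) {
    if (!is.null(n$advice)) {
      list(advice = unlist(n$advice))
    } else {
      list(field = n$field,
           edges = lapply(n$edges, function(e)
             list(values = as.character(unlist(e$values)), target = e$target)))
    }
  })
  guideline_ruleset(name = x$name, root = x$root, nodes = nodes)
}

#' @rdname read_ruleset
#' @export
write_ruleset <- function(ruleset, path) {
  nodes <- lapply(ruleset$nodes, function(n) {
    if (is_leaf_node(n)) list(advice = as.list(n$advice))
    else list(field = n$field,
              edges = lapply(n$edges, function(e)
                list(values = as.list(as.character(e$values)), target = e$target)))
  })
  jsonlite::write_json(list(name = ruleset$name, root = ruleset$root,
                            nodes = nodes),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Packaged rulesets
#'
#' `packaged_ruleset()` loads one of the ruleset files shipped under
#' `inst/extdata`: the Dutch adjuvant colon-cancer tree, or a synthetic,
#' user-editable NCCN-style template (a placeholder structure for encoding a
#' second guideline; it is not a transcription of any published NCCN table).
#'
#' @param which `"dutch"` or `"nccn_template"`.
#' @return A `guideline_ruleset`.
#' @export
packaged_ruleset <- function(which = c("dutch", "nccn_template")) {
  which <- match.arg(which)
  file <- switch(which,
                 dutch = "dutch_adjuvant_colon_ruleset.json",
                 nccn_template = "nccn_style_template_synthetic.json")
  read_ruleset(system.file("extdata", file, package = "cdssaudit",
                           mustWork = TRUE))
}
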