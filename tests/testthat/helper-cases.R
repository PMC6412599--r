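# Case builder with neutral defaults: a low-risk stage II (T3 N0) patient,
# MSS, no contraindication, all held-constant points at normal/absent.
make_case <- function(case_id = "c1", age = 60L, functional_status = 0L,
                      pt_stage = "T3", pn_stage = "N0",
                      nodes_examined = "GE10",
                      differentiation = "WELL_MODERATE",
                      vascular_invasion = FALSE,
                      obstruction_or_perforation = FALSE,
                      msi_status = "MSS",
                      oxaliplatin_contraindicated = FALSE,
                      serious_liver_disease = FALSE,
                      serious_kidney_disease = FALSE,
                      resection_margin = "NEGATIVE",
                      perineural_invasion = FALSE) {
  data.frame(case_id = case_id, age = age, functional_status = functional_status,
             pt_stage = pt_stage, pn_stage = pn_stage,
             nodes_examined = nodes_examined, differentiation = differentiation,
             vascular_invasion = vascular_invasion,
             obstruction_or_perforation = obstruction_or_perforation,
             msi_status = msi_status,
             oxaliplatin_contraindicated = oxaliplatin_contraindicated,
             serious_liver_disease = serious_liver_disease,
             serious_kidney_disease = serious_kidney_disease,
             resection_margin = resection_margin,
             perineural_invasion = perineural_invasion,
             stringsAsFactors = FALSE)
}

adv_chr <- function(advice) stats::setNames(as.character(advice), names(advice))

# Advice with an explicit total assignment, bypassing no invariants.
adv_of <- function(..., source = "GUIDELINE") {
  treatment_advice(c(...), source = source)
}

# Uniformly random total advice (for property tests); caller sets the seed.
random_advice <- function(source = "GUIDELINE") {
  cats <- sample(advice_categories(), 6, replace = TRUE)
  treatment_advice(stats::setNames(cats, default_catalogue()$code),
                   source = source)
}

# Small plan: only pT and pN tested (12 cases), everything else constant.
tiny_plan <- function(mode = "FULL_FACTORIAL",
                      pt_values = c("T1", "T2", "T3", "T4"),
                      pn_values = c("N0", "N1", "N2")) {
  enumeration_plan(
    list(decision_point("age", constant = 60L),
         decision_point("functional_status", constant = 0L),
         decision_point("pt_stage", values = pt_values),
         decision_point("pn_stage", values = pn_values),
         decision_point("nodes_examined", constant = "GE10"),
         decision_point("differentiation", constant = "WELL_MODERATE"),
         decision_point("vascular_invasion", constant = FALSE),
         decision_point("obstruction_or_perforation", constant = FALSE),
         decision_point("msi_status", constant = "MSS"),
         decision_point("oxaliplatin_contraindicated", constant = FALSE),
         decision_point("serious_liver_disease", constant = FALSE),
         decision_point("serious_kidney_disease", constant = FALSE),
         decision_point("resection_margin", constant = "NEGATIVE"),
         decision_point("perineural_invasion", constant = FALSE)),
    mode = mode,
    guideline_point_names = c("pt_stage", "pn_stage"),
    advisor_point_names = c("pt_stage", "pn_stage"))
}

modifyList_points <- function(points, replacements) {
  for (nm in names(replacements)) points[[nm]] <- replacements[[nm]]
  unname(points)
}

# The full-factorial default case set is used by several files; enumerate once.
default_factorial_cases <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- enumerate_cases(default_plan())
    cache
  }
})
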