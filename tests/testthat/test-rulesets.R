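test_that("derive_stage implements the TNM stage groups and partitions cases", {
  expect_equal(derive_stage(make_case(pt_stage = "T2", pn_stage = "N0")), "I")
  expect_equal(derive_stage(make_case(pt_stage = "T3", pn_stage = "N0")), "II")
  expect_equal(derive_stage(make_case(pt_stage = "T1", pn_stage = "N2")), "III")
  # total and single-valued over the whole factorial space
  stage <- derive_stage(default_factorial_cases())
  expect_true(all(stage %in% c("I", "II", "III")))
  expect_length(stage, nrow(default_factorial_cases()))
})

test_that("is_high_risk_stage_ii detects each risk feature and rejects misuse", {
  base <- make_case()  # T3 N0, no features
  expect_false(is_high_risk_stage_ii(base))
  expect_true(is_high_risk_stage_ii(make_case(pt_stage = "T4")))
  expect_true(is_high_risk_stage_ii(make_case(nodes_examined = "LT10")))
  expect_true(is_high_risk_stage_ii(make_case(differentiation = "POOR_UNDIFF")))
  expect_true(is_high_risk_stage_ii(make_case(vascular_invasion = TRUE)))
  expect_true(is_high_risk_stage_ii(make_case(obstruction_or_perforation = TRUE)))
  expect_error(is_high_risk_stage_ii(make_case(pn_stage = "N1")), "non-stage-II")
})

test_that("dutch_advice encodes the adjuvant logic branch by branch", {
  chemo <- setdiff(default_catalogue()$code, "OBSERVATION")
  obs_only <- function(a) {
    expect_equal(unname(a[["OBSERVATION"]]), "R")
    expect_true(all(adv_chr(a)[chemo] == "NR"))
  }
  # stage I and low-risk stage II: observation only
  obs_only(dutch_advice(make_case(pt_stage = "T1", pn_stage = "N0")))
  obs_only(dutch_advice(make_case()))
  # high-risk stage II, MSS, no contraindication: doublets for consideration
  a <- dutch_advice(make_case(pt_stage = "T4"))
  expect_equal(unname(a[c("OBSERVATION", "CAPOX", "FOLFOX")]), c("R", "C", "C"))
  expect_true(all(a[c("CAPE_MONO", "FU_LV_MONO", "OTHER_SYSTEMIC")] == "NR"))
  # high-risk stage II blocked by MSI or contraindication
  obs_only(dutch_advice(make_case(pt_stage = "T4", msi_status = "MSI")))
  obs_only(dutch_advice(make_case(pt_stage = "T4", oxaliplatin_contraindicated = TRUE)))
  # stage III: doublets recommended regardless of MSI when oxaliplatin is usable
  for (msi in c("MSS", "MSI")) {
    a <- dutch_advice(make_case(pn_stage = "N1", msi_status = msi))
    expect_equal(unname(a[c("CAPOX", "FOLFOX", "OBSERVATION")]), c("R", "R", "NR"))
  }
  # stage III fallbacks under contraindication
  a <- dutch_advice(make_case(pn_stage = "N2", oxaliplatin_contraindicated = TRUE))
  expect_equal(unname(a[c("CAPE_MONO", "FU_LV_MONO", "CAPOX", "OBSERVATION")]),
               c("R", "R", "NR", "NR"))
  obs_only(dutch_advice(make_case(pn_stage = "N2", msi_status = "MSI",
                                  oxaliplatin_contraindicated = TRUE)))
})

test_that("dutch_advice is total and ignores age and functional status", {
  cases <- default_factorial_cases()
  set.seed(11)
  for (i in sample(nrow(cases), 25)) {
    case <- cases[i, , drop = FALSE]
    a <- dutch_advice(case)
    expect_setequal(names(a), default_catalogue()$code)
    expect_true(all(a %in% advice_categories()))
    case$age <- 99L
    case$functional_status <- 3L
    expect_identical(adv_chr(dutch_advice(case)), adv_chr(a))
  }
})

test_that("adding a high-risk feature never demotes chemotherapy (monotone risk)", {
  features <- list(
    function(c) { c$pt_stage <- "T4"; c },
    function(c) { c$nodes_examined <- "LT10"; c },
    function(c) { c$differentiation <- "POOR_UNDIFF"; c },
    function(c) { c$vascular_invasion <- TRUE; c },
    function(c) { c$obstruction_or_perforation <- TRUE; c }
  )
  cases <- default_factorial_cases()
  stage2 <- cases[derive_stage(cases) == "II" & cases$msi_status == "MSS" &
                    !cases$oxaliplatin_contraindicated, ]
  chemo <- setdiff(default_catalogue()$code, "OBSERVATION")
  set.seed(7)
  for (i in sample(nrow(stage2), 20)) {
    before <- adv_chr(dutch_advice(stage2[i, , drop = FALSE]))
    for (add in features) {
      after <- adv_chr(dutch_advice(add(stage2[i, , drop = FALSE])))
      demoted <- before[chemo] %in% c("R", "C") & after[chemo] == "NR"
      expect_false(any(demoted))
    }
  }
})

test_that("evaluate_ruleset walks edges, handles the degenerate tree, flags gaps", {
  one_leaf <- guideline_ruleset("trivial", root = "L",
                                nodes = list(L = list(advice = c(OBSERVATION = "R"))))
  a <- evaluate_ruleset(one_leaf, make_case())
  expect_equal(unname(a[["OBSERVATION"]]), "R")
  expect_true(all(a[setdiff(names(a), "OBSERVATION")] == "NR"))  # NR-coercion

  gappy <- guideline_ruleset("gap", root = "n", nodes = list(
    n = list(field = "pn_stage",
             edges = list(list(values = "N0", target = "L"))),
    L = list(advice = c(OBSERVATION = "R"))))
  expect_error(evaluate_ruleset(gappy, make_case(pn_stage = "N1")),
               "ruleset defect")
})

test_that("the packaged Dutch tree matches the hard-coded oracle on sampled cases", {
  tree <- dutch_tree()
  packaged <- packaged_ruleset("dutch")
  cases <- default_factorial_cases()
  set.seed(3)
  for (i in sample(nrow(cases), 40)) {
    case <- cases[i, , drop = FALSE]
    expect_identical(adv_chr(evaluate_ruleset(tree, case)),
                     adv_chr(dutch_advice(case)))
    expect_identical(adv_chr(evaluate_ruleset(packaged, case)),
                     adv_chr(dutch_advice(case)))
  }
})

test_that("validate_ruleset accepts the packaged trees and reports each defect kind", {
  expect_equal(nrow(validate_ruleset(dutch_tree())), 0L)
  expect_equal(nrow(validate_ruleset(packaged_ruleset("dutch"))), 0L)
  expect_equal(nrow(validate_ruleset(packaged_ruleset("nccn_template"))), 0L)

  leaf <- list(advice = c(OBSERVATION = "R"))
  overlap <- guideline_ruleset("overlap", "n", list(
    n = list(field = "pn_stage",
             edges = list(list(values = c("N0", "N1"), target = "L"),
                          list(values = c("N1", "N2"), target = "L"))),
    L = leaf))
  expect_equal(validate_ruleset(overlap)$type, "overlap")

  gap <- guideline_ruleset("gap", "n", list(
    n = list(field = "pn_stage",
             edges = list(list(values = "N0", target = "L"))),
    L = leaf))
  expect_equal(validate_ruleset(gap)$type, "gap")

  cyc <- guideline_ruleset("cycle", "a", list(
    a = list(field = "vascular_invasion",
             edges = list(list(values = "TRUE", target = "b"),
                          list(values = "FALSE", target = "L"))),
    b = list(field = "msi_status",
             edges = list(list(values = c("MSS", "MSI"), target = "a"))),
    L = leaf))
  expect_true("cycle" %in% validate_ruleset(cyc)$type)

  cont <- guideline_ruleset("cont", "n", list(
    n = list(field = "age", edges = list(list(values = "45", target = "L"))),
    L = leaf))
  expect_true("unsupported_field" %in% validate_ruleset(cont)$type)

  orphan <- guideline_ruleset("orphan", "L", list(L = leaf, lost = leaf))
  expect_true("unreachable" %in% validate_ruleset(orphan)$type)

  expect_equal(validate_ruleset(
    guideline_ruleset("noroot", "absent", list(L = leaf)))$type, "missing_root")
})

test_that("ruleset JSON IO round-trips and the packaged file equals the constructor", {
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset(dutch_tree(), path)
  back <- read_ruleset(path)
  expect_equal(nrow(validate_ruleset(back)), 0L)
  cases <- default_factorial_cases()
  set.seed(5)
  for (i in sample(nrow(cases), 15)) {
    case <- cases[i, , drop = FALSE]
    expect_identical(adv_chr(evaluate_ruleset(back, case)),
                     adv_chr(dutch_advice(case)))
  }
  # the shipped fixture is the constructor's tree, byte-normalized
  shipped <- system.file("extdata", "dutch_adjuvant_colon_ruleset.json",
                         package = "cdssaudit")
  expect_identical(readLines(shipped), readLines(path))
})

test_that("treatment_advice enforces totality, NR-coercion and category validity", {
  a <- treatment_advice(c(CAPOX = "R"), source = "ADVISOR")
  expect_equal(attr(a, "source"), "ADVISOR")
  expect_equal(unname(a[["CAPOX"]]), "R")
  expect_true(all(a[setdiff(names(a), "CAPOX")] == "NR"))
  expect_error(treatment_advice(c(NOT_AN_OPTION = "R")), "unknown option")
  expect_error(treatment_advice(c(CAPOX = "MAYBE")), "invalid advice categories")
})
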