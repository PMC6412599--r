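test_that("the default matrix scores agreement +2 and graded disagreement down to -2", {
  m <- default_matrix()
  expect_equal(m["R", "R"], 2L)
  expect_equal(m["C", "C"], 2L)
  expect_equal(m["NR", "NR"], 2L)
  expect_equal(m["NR", "R"], -2L)
  expect_equal(m["R", "NR"], -2L)
  expect_equal(m["NR", "C"], -1L)
  expect_equal(m["C", "NR"], -1L)
  expect_equal(m["R", "C"], 1L)
  expect_equal(m["C", "R"], 1L)
})

test_that("score_matrix enforces the structural invariants", {
  cats <- advice_categories()
  cells <- matrix(2L, 3, 3, dimnames = list(guideline = cats, advisor = cats))
  cells["R", "NR"] <- -2L; cells["NR", "R"] <- -2L
  expect_s3_class(score_matrix(cells), "score_matrix")
  bad <- cells; bad["R", "R"] <- 1L
  expect_error(score_matrix(bad), "diagonal")
  bad <- cells; bad["R", "NR"] <- -1L
  expect_error(score_matrix(bad), "must equal -2")
  bad <- cells; bad["C", "NR"] <- -5L
  expect_error(score_matrix(bad), "\\[-2, 2\\]")
  expect_error(score_matrix(matrix(0L, 2, 2)), "3x3")
})

test_that("score_case sums matrix cells over the catalogue", {
  g <- dutch_advice(make_case(pt_stage = "T1"))  # stage I: OBS=R, chemo NR
  identical_adv <- treatment_advice(adv_chr(g), source = "ADVISOR")
  expect_equal(score_case(g, identical_adv)$overall_score, 12L)

  flipped <- adv_chr(g)
  flipped[flipped == "R"] <- "x"; flipped[flipped == "NR"] <- "R"; flipped[flipped == "x"] <- "NR"
  expect_equal(score_case(g, treatment_advice(flipped, source = "ADVISOR"))$overall_score,
               -12L)

  one_off <- adv_chr(g)
  one_off[["OBSERVATION"]] <- "C"  # guideline R, advisor C -> +1
  sc <- score_case(g, treatment_advice(one_off, source = "ADVISOR"))
  expect_equal(sc$overall_score, 11L)
  expect_equal(unname(sc$per_option_scores[["OBSERVATION"]]), 1L)

  expect_error(score_case(g, structure(c(OBSERVATION = "R"), class = "treatment_advice")),
               "not total")
})

test_that("flags mark advisor-endorsed chemotherapy that the guideline prohibits", {
  g <- dutch_advice(make_case(pt_stage = "T1"))  # all chemo NR
  expect_equal(assign_flag(g, adv_of(CAPOX = "R", source = "ADVISOR")), "RED")
  expect_equal(assign_flag(g, adv_of(OBSERVATION = "R", CAPOX = "C",
                                     source = "ADVISOR")), "ORANGE")
  # red precedence when both hold
  expect_equal(assign_flag(g, adv_of(CAPOX = "R", FOLFOX = "C",
                                     source = "ADVISOR")), "RED")
  expect_equal(assign_flag(g, treatment_advice(adv_chr(g), source = "ADVISOR")),
               "NONE")
  # observation is exempt: advisor recommending OBSERVATION against a
  # guideline prohibition of it is not a chemotherapy-safety flag
  g3 <- dutch_advice(make_case(pn_stage = "N1"))  # OBSERVATION=NR
  expect_equal(assign_flag(g3, adv_of(OBSERVATION = "R", CAPOX = "R",
                                      FOLFOX = "R", source = "ADVISOR")), "NONE")
})

test_that("identity, bound and degradation laws hold (property sweep)", {
  m <- default_matrix()
  cat6 <- default_catalogue()
  set.seed(31)
  for (rep in 1:200) {
    g <- random_advice()
    a <- random_advice(source = "ADVISOR")
    sc <- score_case(g, a, m, cat6)$overall_score
    expect_gte(sc, -12L); expect_lte(sc, 12L)
    # identity law
    expect_equal(score_case(g, treatment_advice(adv_chr(g), source = "ADVISOR"),
                            m, cat6)$overall_score, 12L)
  }
  # degradation monotonicity: the diagonal is each row's strict maximum, so
  # moving any single option off-diagonal strictly lowers the overall score
  g <- random_advice()
  base <- score_case(g, treatment_advice(adv_chr(g), source = "ADVISOR"))$overall_score
  for (code in cat6$code) {
    for (other in setdiff(advice_categories(), g[[code]])) {
      degraded <- adv_chr(g); degraded[[code]] <- other
      sc <- score_case(g, treatment_advice(degraded, source = "ADVISOR"))$overall_score
      expect_lt(sc, base)
    }
  }
})

test_that("flag precedence holds on every qualifying random pair", {
  set.seed(47)
  hits <- 0L
  for (rep in 1:300) {
    g <- random_advice()
    a <- random_advice(source = "ADVISOR")
    chemo <- setdiff(names(g), "OBSERVATION")
    red_q <- any(g[chemo] == "NR" & a[chemo] == "R")
    orange_q <- any(g[chemo] == "NR" & a[chemo] == "C")
    expected <- if (red_q) "RED" else if (orange_q) "ORANGE" else "NONE"
    expect_equal(assign_flag(g, a), expected)
    if (red_q && orange_q) hits <- hits + 1L
  }
  expect_gt(hits, 10L)  # the sweep actually exercised the precedence branch
})

test_that("aggregate_results summarizes scores, histograms and flag percentages", {
  one <- data.frame(case_id = "c1", stage = "II", overall_score = 7L,
                    flag = "NONE", stringsAsFactors = FALSE)
  s <- aggregate_results(one)
  expect_equal(c(s$score_min, s$score_median, s$score_max), c(7L, 7L, 7L))

  three <- data.frame(case_id = c("a", "b", "c"), stage = c("I", "II", "III"),
                      overall_score = c(3L, -4L, 12L),
                      flag = c("RED", "ORANGE", "NONE"), stringsAsFactors = FALSE)
  s <- aggregate_results(three)
  expect_equal(s$score_min, -4L)
  expect_equal(s$score_median, 3L)
  expect_equal(s$score_max, 12L)
  expect_equal(s$histogram_by_stage$II, c(`-4` = 1L))
  expect_equal(unname(s$flag_counts), c(1L, 1L, 1L))

  # even count: lower middle value, and the convention is stated
  four <- data.frame(case_id = letters[1:4], stage = "I",
                     overall_score = c(1L, 2L, 8L, 9L), flag = "NONE",
                     stringsAsFactors = FALSE)
  expect_equal(aggregate_results(four)$score_median, 2L)
  expect_match(aggregate_results(four)$median_convention, "lower middle")

  # empty input allowed
  s0 <- aggregate_results(three[0, ])
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$score_median))
})

test_that("flag percentages round to integers and sum to 100 +/- 1", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(10:400, 1)
    res <- data.frame(case_id = as.character(seq_len(n)), stage = "II",
                      overall_score = 0L,
                      flag = sample(c("RED", "ORANGE", "NONE"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    s <- aggregate_results(res)
    expect_equal(sum(s$flag_counts), n)
    expect_lte(abs(sum(s$flag_percent) - 100), 1)
  }
})

test_that("score matrices round-trip through JSON and the fixture matches", {
  path <- withr::local_tempfile(fileext = ".json")
  write_score_matrix(default_matrix(), path)
  expect_equal(read_score_matrix(path), default_matrix())
  shipped <- system.file("extdata", "default_matrix.json", package = "cdssaudit")
  expect_equal(read_score_matrix(shipped), default_matrix())
})
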