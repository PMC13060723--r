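test_that("build_timelines applies the exclusion cascade", {
  pats <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    sex = c("female", "male", "female", "male"),
    birth_date = as.Date(c("1950-01-01", "1950-01-01", "1981-01-01",
                           "1950-01-01")),
    bmi = NA_real_, seifa_percentile = NA_integer_,
    stringsAsFactors = FALSE)
  enc <- data.frame(
    patient_id = c("A", "B", "C", "D", "D"),
    encounter_date = as.Date(c("2012-03-01", "2012-03-01", "2012-03-01",
                               "2012-03-01", NA)),
    reason_text = c("jaundice",          # A: kept
                    "jaundice",          # B: C25 before first event
                    "jaundice",          # C: aged 31 at presentation
                    "flu vaccination",   # D: no relevant symptom
                    "jaundice"),         # D: dropped (missing date)
    stringsAsFactors = FALSE)
  reg <- data.frame(patient_id = "B", diagnosis_date = as.Date("2011-01-01"),
                    icd10_code = "C25.9", stringsAsFactors = FALSE)
  tls <- build_timelines(mk_tables(patients = pats, encounters = enc,
                                   registry = reg),
                         default_lexicon())
  expect_identical(names(tls), "A")
  flow <- attr(tls, "flow")
  expect_identical(flow$encounters_dropped_incomplete, 1L)
  expect_identical(flow$patients_excluded_prior_cancer, 1L)
  expect_identical(flow$final_cohort, 1L)
  expect_s3_class(tls$A, "pc_timeline")
  expect_identical(tls$A$events$symptom_code, "jaundice")
})

test_that("orphan child rows are skipped with a warning", {
  pats <- data.frame(patient_id = "A", sex = "female",
                     birth_date = as.Date("1950-01-01"), bmi = NA_real_,
                     seifa_percentile = NA_integer_, stringsAsFactors = FALSE)
  enc <- data.frame(patient_id = c("A", "GHOST"),
                    encounter_date = as.Date("2012-03-01"),
                    reason_text = "jaundice", stringsAsFactors = FALSE)
  expect_warning(
    tls <- build_timelines(mk_tables(patients = pats, encounters = enc),
                           default_lexicon()),
    "unknown patient_id")
  expect_identical(names(tls), "A")
})

test_that("single qualifying event flags at entry with index = entry", {
  tl <- mk_timeline("2012-01-01", "jaundice")
  ev <- evaluate_tool(tl, tiny_ruleset())
  expect_true(ev$eligible)
  expect_true(ev$flagged)
  expect_identical(ev$flag_date, as.Date("2012-01-01"))
  expect_identical(ev$index_date, as.Date("2012-01-01"))
  expect_false(ev$outcome_cancer_12m)
})

test_that("a combination outside the accumulation window never flags", {
  tl <- mk_timeline(c("2012-01-01", "2013-02-05"), c("uwl", "abd_pain"))
  ev <- evaluate_tool(tl, tiny_ruleset())
  expect_true(ev$eligible)
  expect_false(ev$flagged)
  # index = last qualifying event inside the window = entry itself
  expect_identical(ev$index_date, as.Date("2012-01-01"))
  want <- brute_force_evaluate(tl, tiny_ruleset())
  expect_identical(ev$flagged, want$flagged)
  expect_identical(ev$index_date, want$index)
})

test_that("collection stops at diagnosis before flag criteria complete", {
  tl <- mk_timeline(c("2012-01-01", "2012-01-21"), c("uwl", "abd_pain"),
                    dx = "2012-01-11")
  ev <- evaluate_tool(tl, tiny_ruleset())
  expect_false(ev$flagged)
  expect_identical(ev$index_date, as.Date("2012-01-01"))
  expect_true(ev$outcome_cancer_12m)
  expect_match(ev$censoring_note, "diagnosis")
})

test_that("incremental evaluator matches the brute-force oracle on random timelines", {
  set.seed(123)
  cfg <- cohort_config()
  tools <- c(list(tiny = tiny_ruleset()),
             default_tools()[c("eRAT", "QCancer")])
  n_bad <- 0
  for (rep in 1:1000) {
    tl <- random_timeline()
    tool <- if (rep %% 3 == 0) random_ruleset() else
      tools[[sample(length(tools), 1)]]
    got <- evaluate_tool(tl, tool, cfg)
    want <- brute_force_evaluate(tl, tool, cfg)
    if (!isTRUE(all.equal(got$eligible, want$eligible))) n_bad <- n_bad + 1
    if (got$eligible && want$eligible) {
      same <- identical(got$flagged, want$flagged) &&
        identical(got$index_date, want$index) &&
        identical(got$outcome_cancer_12m, want$outcome) &&
        (!got$flagged || identical(got$flag_date, want$flag_date))
      if (!same) n_bad <- n_bad + 1
    }
  }
  expect_identical(n_bad, 0)
})

test_that("evaluation is translation-equivariant in time", {
  set.seed(99)
  cfg <- cohort_config(study_start = "1990-01-01", study_end = "2030-01-01",
                       registry_end = "2031-01-01")
  for (rep in 1:50) {
    tl <- random_timeline()
    k <- sample(c(-400, -30, 30, 400), 1)
    tl2 <- tl
    tl2$events$event_date <- tl$events$event_date + k
    if (!is.null(tl$diagnosis)) {
      tl2$diagnosis$date <- tl$diagnosis$date + k
    }
    tl2$birth_date <- tl$birth_date + k  # keep age at entry identical
    e1 <- evaluate_tool(tl, tiny_ruleset(), cfg)
    e2 <- evaluate_tool(tl2, tiny_ruleset(), cfg)
    expect_identical(e1$flagged, e2$flagged)
    expect_identical(e2$entry_date, e1$entry_date + k)
    expect_identical(e2$index_date, e1$index_date + k)
    expect_identical(e1$outcome_cancer_12m, e2$outcome_cancer_12m)
  }
})

test_that("no evaluation uses events after its own stop time", {
  # flag at entry: a later event that would also flag must not move the date
  tl <- mk_timeline(c("2012-01-01", "2012-06-01"), c("jaundice", "jaundice"))
  ev <- evaluate_tool(tl, tiny_ruleset())
  expect_identical(ev$flag_date, as.Date("2012-01-01"))
  # diagnosis stop: post-diagnosis events are invisible to the index date
  tl2 <- mk_timeline(c("2012-01-01", "2012-09-01"), c("uwl", "uwl"),
                     dx = "2012-03-01")
  ev2 <- evaluate_tool(tl2, tiny_ruleset())
  expect_identical(ev2$index_date, as.Date("2012-01-01"))
})

test_that("pre-COVID filter keeps only early entries and is idempotent", {
  cfg <- cohort_config()
  tls <- list(
    early = mk_timeline("2015-01-01", "jaundice", id = "early"),
    late = mk_timeline("2020-06-01", "jaundice", id = "late"))
  class(tls) <- "list"
  out <- apply_precovid_filter(tls, cfg)
  expect_identical(names(out), "early")
  expect_identical(names(apply_precovid_filter(out, cfg)), "early")
  expect_length(apply_precovid_filter(list(), cfg), 0)
})

test_that("unknown-sex patients are ineligible for the risk model but not rule tools", {
  tl <- mk_timeline("2012-01-01", "abd_pain", sex = "unknown")
  qc <- default_tools()$QCancer
  expect_false(evaluate_tool(tl, qc)$eligible)
  expect_true(evaluate_tool(tl, tiny_ruleset())$eligible)
  # age outside the risk-model range is an ineligibility marker too
  old <- mk_timeline("2012-01-01", "abd_pain", birth = "1915-01-01")
  expect_false(evaluate_tool(old, qc)$eligible)
})
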