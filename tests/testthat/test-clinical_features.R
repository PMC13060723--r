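path_rows <- function(dates, values, analyte = "hba1c", units = "%",
                      pid = "P1") {
  data.frame(patient_id = rep_len(pid, length(dates)),
             result_date = as.Date(dates),
             analyte = rep_len(analyte, length(dates)), value = values,
             units = rep_len(units, length(dates)), stringsAsFactors = FALSE)
}
rx_rows <- function(dates, meds, pid = "P1") {
  data.frame(patient_id = rep_len(pid, length(dates)),
             script_date = as.Date(dates),
             medication_name = meds, stringsAsFactors = FALSE)
}
no_rx <- rx_rows(character(0), character(0))

test_that("normalise_hba1c applies the NGSP/IFCC master equation", {
  expect_equal(normalise_hba1c(48, "mmol/mol"), 0.09148 * 48 + 2.152)
  expect_equal(round(normalise_hba1c(48, "mmol/mol"), 2), 6.54)
  expect_equal(normalise_hba1c(6.5, "%"), 6.5)
  expect_error(normalise_hba1c(0, "%"), "positive")
  expect_error(normalise_hba1c(6.5, "mg/dL"), "unknown HbA1c units")
})

test_that("diabetes route A: single diagnostic HbA1c", {
  cfg <- feature_config()
  ev <- detect_new_onset_diabetes(path_rows("2015-03-01", 7.2), no_rx, cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$event_date, as.Date("2015-03-01"))
  expect_identical(ev$symptom_code, "new_onset_diabetes")
  expect_identical(ev$source, "pathology_or_prescription")
  # mmol/mol dialect triggers identically after normalisation
  ev2 <- detect_new_onset_diabetes(path_rows("2015-03-01", 60,
                                             units = "mmol/mol"), no_rx, cfg)
  expect_identical(ev2$event_date, as.Date("2015-03-01"))
})

test_that("diabetes route B: raised pair > 3 months apart, event at second", {
  cfg <- feature_config()
  p <- path_rows(c("2015-01-01", "2015-05-01"), c(6.2, 6.3))
  ev <- detect_new_onset_diabetes(p, no_rx, cfg)
  expect_identical(ev$event_date, as.Date("2015-05-01"))
  # below the minimum gap: no event
  p2 <- path_rows(c("2015-01-01", "2015-03-01"), c(6.2, 6.3))
  expect_identical(nrow(detect_new_onset_diabetes(p2, no_rx, cfg)), 0L)
})

test_that("earliest route wins and prior evidence disqualifies new onset", {
  cfg <- feature_config()
  p <- path_rows("2015-01-01", 7.0)
  r <- rx_rows("2014-06-01", "metformin")
  ev <- detect_new_onset_diabetes(p, r, cfg)
  expect_identical(ev$event_date, as.Date("2014-06-01"))
  # trigger before study_start => prevalent diabetes, excluded
  expect_identical(nrow(detect_new_onset_diabetes(
    p, r, cfg, study_start = as.Date("2014-07-01"))), 0L)
  # brand names match case-insensitively
  evb <- detect_new_onset_diabetes(path_rows(character(0), numeric(0)),
                                   rx_rows("2016-02-01", "DIABEX 500mg"),
                                   cfg)
  expect_identical(evb$event_date, as.Date("2016-02-01"))
  # non-diabetes scripts never trigger
  expect_identical(nrow(detect_new_onset_diabetes(
    path_rows(character(0), numeric(0)),
    rx_rows("2016-02-01", "atorvastatin"), cfg)), 0L)
})

test_that("route-B detector agrees with the O(n^2) pair oracle", {
  cfg <- feature_config()
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(2:10, 1)
    dates <- as.Date("2014-01-01") + sample(0:900, n)
    vals <- round(runif(n, 5.2, 7.5), 1)
    n_rx <- sample(0:2, 1)
    rx_dates <- as.Date("2014-01-01") + sample(0:900, n_rx)
    meds <- sample(c("metformin", "gliclazide"), n_rx, replace = TRUE)
    got <- detect_new_onset_diabetes(path_rows(dates, vals),
                                     rx_rows(rx_dates, meds), cfg)
    want <- diabetes_oracle(dates, vals, rx_dates, cfg)
    if (is.na(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$event_date, want)
    }
  }
})

test_that("detection is idempotent, order-independent, and one event per patient", {
  cfg <- feature_config()
  p <- rbind(path_rows(c("2015-01-01", "2015-06-01", "2016-01-01"),
                       c(6.2, 6.3, 8.0)),
             path_rows("2015-02-01", 7.5, pid = "P2"))
  r <- rx_rows("2015-09-01", "Januvia")
  ev1 <- detect_new_onset_diabetes(p, r, cfg)
  ev2 <- detect_new_onset_diabetes(p[sample(nrow(p)), ], r, cfg)
  expect_identical(ev1, ev2)
  expect_identical(nrow(ev1), 2L)
  expect_false(anyDuplicated(ev1$patient_id) > 0)
})

test_that("biochemical jaundice uses a strict > threshold", {
  cfg <- feature_config()
  above <- detect_biochemical_jaundice(
    path_rows("2015-01-01", 35, analyte = "bilirubin_total",
              units = "umol/L"), cfg)
  expect_identical(above$symptom_code, "jaundice")
  expect_identical(above$source, "pathology")
  at <- detect_biochemical_jaundice(
    path_rows("2015-01-01", 21, analyte = "bilirubin_total",
              units = "umol/L"), cfg)
  expect_identical(nrow(at), 0L)
  # hba1c rows are never mistaken for bilirubin
  expect_identical(nrow(detect_biochemical_jaundice(
    path_rows("2015-01-01", 50), cfg)), 0L)
})

test_that("same-day text and biochemical jaundice merge to one event", {
  cfg <- feature_config()
  text_ev <- extract_symptom_events(
    data.frame(patient_id = "P1", encounter_date = as.Date("2015-01-01"),
               reason_text = "jaundice", stringsAsFactors = FALSE),
    default_lexicon())
  lab_ev <- detect_biochemical_jaundice(
    path_rows("2015-01-01", 40, analyte = "bilirubin_total",
              units = "umol/L"), cfg)
  merged <- merge_symptom_events(text_ev, lab_ev)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$source, "text")  # text wins the dedup priority
})

test_that("detectors are antitone in their thresholds", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    dates <- as.Date("2013-01-01") + sample(0:1500, n)
    hvals <- round(runif(n, 5, 9), 1)
    bvals <- round(runif(n, 5, 80))
    thr <- sort(runif(2, 5.5, 7.5))
    n_hi <- nrow(detect_new_onset_diabetes(
      path_rows(dates, hvals), no_rx,
      feature_config(hba1c_threshold_pct = thr[2],
                     hba1c_raised_pct = thr[2])))
    n_lo <- nrow(detect_new_onset_diabetes(
      path_rows(dates, hvals), no_rx,
      feature_config(hba1c_threshold_pct = thr[1],
                     hba1c_raised_pct = thr[1])))
    expect_lte(n_hi, n_lo)
    bthr <- sort(runif(2, 10, 60))
    b_hi <- nrow(detect_biochemical_jaundice(
      path_rows(dates, bvals, analyte = "bilirubin_total", units = "umol/L"),
      feature_config(bilirubin_upper_limit_umol = bthr[2])))
    b_lo <- nrow(detect_biochemical_jaundice(
      path_rows(dates, bvals, analyte = "bilirubin_total", units = "umol/L"),
      feature_config(bilirubin_upper_limit_umol = bthr[1])))
    expect_lte(b_hi, b_lo)
  }
})
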