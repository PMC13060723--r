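# Independent oracles, deliberately written as plain re-derivations of the
# contracts (brute force / enumeration), not calls into the code paths they
# check.

# Brute-force windowed tool evaluation: enumerate every event-date cut and
# test the tool on the accumulated set; first flagging cut wins.
brute_force_evaluate <- function(tl, tool, config = cohort_config()) {
  codes <- tool_codes(tool)
  qual <- tl$events[tl$events$symptom_code %in% codes, , drop = FALSE]
  if (nrow(qual) == 0) return(list(eligible = FALSE))
  entry <- min(qual$event_date)
  age_entry <- as.numeric(entry - tl$birth_date) / 365.25
  if (inherits(tool, "pc_riskmodel")) {
    if (!tl$sex %in% c("male", "female") || age_entry < tool$age_min ||
          age_entry > tool$age_max) {
      return(list(eligible = FALSE))
    }
  }
  dx <- if (is.null(tl$diagnosis)) as.Date(NA) else tl$diagnosis$date
  if (!is.na(dx) && dx < entry) return(list(eligible = FALSE))
  stop_date <- entry + config$accumulation_window_days
  if (!is.na(dx) && dx < stop_date) stop_date <- dx

  cuts <- sort(unique(qual$event_date[qual$event_date <= stop_date]))
  flag_date <- as.Date(NA)
  for (d in cuts) {
    acc <- unique(qual$symptom_code[qual$event_date <= d])
    flagged_here <- if (inherits(tool, "pc_ruleset")) {
      any(vapply(tool$clauses, function(cl) {
        all(cl$required_symptoms %in% acc) &&
          (is.null(cl$min_age) || age_entry >= cl$min_age) &&
          (is.null(cl$max_age) || age_entry <= cl$max_age) &&
          (is.null(cl$sex) || identical(tl$sex, cl$sex))
      }, logical(1)))
    } else {
      co <- tool$coefficients[[tl$sex]]
      bmi <- if (is.na(tl$bmi)) tool$default_bmi else tl$bmi
      dep <- if (is.na(tl$seifa)) tool$default_deprivation else tl$seifa
      lp <- co[["intercept"]] +
        (if ("age_decade" %in% names(co)) co[["age_decade"]] * age_entry / 10 else 0) +
        (if ("bmi_per5" %in% names(co)) co[["bmi_per5"]] * (bmi - 25) / 5 else 0) +
        (if ("deprivation_pct" %in% names(co)) co[["deprivation_pct"]] * dep else 0) +
        sum(co[intersect(acc, names(co))])
      1 / (1 + exp(-lp)) > tool$threshold
    }
    if (flagged_here) { flag_date <- as.Date(d, origin = "1970-01-01"); break }
  }
  flagged <- !is.na(flag_date)
  index <- if (flagged) flag_date else
    max(qual$event_date[qual$event_date <= stop_date])
  outcome <- !is.na(dx) && as.numeric(dx - index) >= 0 &&
    as.numeric(dx - index) <= config$followup_window_days
  list(eligible = TRUE, entry = entry, flagged = flagged,
       flag_date = flag_date, index = index, outcome = outcome)
}

# O(n^2) route-B oracle plus min-over-routes for new-onset diabetes on one
# patient's records
diabetes_oracle <- function(hba1c_dates, hba1c_pct, script_dates, cfg,
                            study_start = NULL) {
  cand <- as.Date(character(0))
  cand <- c(cand, hba1c_dates[hba1c_pct >= cfg$hba1c_threshold_pct])
  raised <- sort(hba1c_dates[hba1c_pct >= cfg$hba1c_raised_pct])
  if (length(raised) >= 2) {
    best <- as.Date(NA)
    for (i in seq_along(raised)) {
      for (j in seq_along(raised)) {
        if (i == j) next
        gap <- as.numeric(raised[j] - raised[i])
        if (gap >= cfg$paired_result_min_gap_days &&
              (is.na(best) || raised[j] < best)) {
          best <- raised[j]
        }
      }
    }
    if (!is.na(best)) cand <- c(cand, best)
  }
  cand <- c(cand, script_dates)
  if (length(cand) == 0) return(as.Date(NA))
  ev <- min(cand)
  if (!is.null(study_start) && ev < as.Date(study_start)) return(as.Date(NA))
  ev
}

# direct beta-quantile Clopper-Pearson, written independently
cp_oracle <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  c(if (x == 0) 0 else qbeta(a, x, n - x + 1),
    if (x == n) 1 else 1 - qbeta(a, n - x, x + 1))
}
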