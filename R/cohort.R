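# Cohort construction: eligibility, entry, accumulation window, stopping,
# index date and follow-up logic.

#' Cohort configuration
#'
#' @param study_start,study_end Study window for qualifying presentations
#'   (defaults 2007-07-01 / 2021-06-30).
#' @param registry_end End of registry follow-up (default 2022-06-30).
#' @param age_min,age_max Eligible age at presentation (default 40-100).
#' @param accumulation_window_days Days after the first qualifying symptom
#'   during which further symptoms may combine to flag (default 365).
#' @param followup_window_days Days after the index date within which a
#'   registry diagnosis counts as the outcome (default 365; a diagnosis on
#'   the index date itself also counts).
#' @param precovid_end Optional cut-off for the pre-COVID sensitivity
#'   analysis (default 2019-12-31).
#' @return Object of class `pc_cohort_config`.
#' @export
cohort_config <- function(study_start = as.Date("2007-07-01"),
                          study_end = as.Date("2021-06-30"),
                          registry_end = as.Date("2022-06-30"),
                          age_min = 40, age_max = 100,
                          accumulation_window_days = 365L,
                          followup_window_days = 365L,
                          precovid_end = as.Date("2019-12-31")) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  registry_end <- as.Date(registry_end)
  stopifnot(study_start < study_end, study_end <= registry_end,
            accumulation_window_days > 0, followup_window_days > 0,
            age_min < age_max)
  structure(list(study_start = study_start, study_end = study_end,
                 registry_end = registry_end, age_min = age_min,
                 age_max = age_max,
                 accumulation_window_days = as.integer(accumulation_window_days),
                 followup_window_days = as.integer(followup_window_days),
                 precovid_end = if (is.null(precovid_end)) NULL
                                else as.Date(precovid_end)),
            class = "pc_cohort_config")
}

age_at <- function(birth_date, date) {
  as.numeric(difftime(date, birth_date, units = "days")) / 365.25
}

#' Construct a patient event timeline
#'
#' Mostly produced by [build_timelines()]; the constructor is exported so
#' small hand-built timelines can be evaluated directly (worked examples,
#' tests).
#'
#' @param patient_id Identifier.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param birth_date Date of birth.
#' @param events Data frame with `event_date`, `symptom_code`, and
#'   optionally `source`, `provenance`; sorted internally.
#' @param diagnosis Optional list `(date, icd10)`.
#' @param bmi,seifa Optional covariates (NA = missing).
#' @return Object of class `pc_timeline`.
#' @export
timeline <- function(patient_id, sex, birth_date, events, diagnosis = NULL,
                     bmi = NA_real_, seifa = NA_integer_) {
  stopifnot(all(c("event_date", "symptom_code") %in% names(events)))
  assert_canonical_codes(events$symptom_code)
  if (is.null(events$source)) events$source <- "text"
  if (is.null(events$provenance)) events$provenance <- ""
  events$event_date <- as.Date(events$event_date)
  events <- events[order(events$event_date,
                         match(events$symptom_code, canonical_symptoms())), ,
                   drop = FALSE]
  rownames(events) <- NULL
  if (!is.null(diagnosis)) diagnosis$date <- as.Date(diagnosis$date)
  structure(list(patient_id = patient_id, sex = sex,
                 birth_date = as.Date(birth_date), bmi = bmi, seifa = seifa,
                 events = events, diagnosis = diagnosis),
            class = "pc_timeline")
}

#' Build per-patient event timelines from linked tables
#'
#' Merges text-extracted, pathology-derived and prescription-derived
#' symptom events into one date-ordered stream per patient; drops
#' encounters with a missing date or reason; restricts events to the study
#' window and the eligible age band; excludes patients whose pancreatic
#' cancer (C25) diagnosis predates their first qualifying event; and drops
#' patients left with no events. Exclusion-cascade counts are attached as
#' attribute `"flow"`.
#'
#' @param tables A `pc_tables` list.
#' @param lexicon A [symptom_lexicon()].
#' @param feat_config A [feature_config()].
#' @param config A [cohort_config()].
#' @return Named list of `pc_timeline` objects (one per retained patient),
#'   each with `patient_id`, `sex`, `birth_date`, `bmi`, `seifa`, `events`
#'   (data frame) and `diagnosis` (list or NULL); attribute `"flow"` holds
#'   the cascade counts.
#' @export
build_timelines <- function(tables, lexicon, feat_config = feature_config(),
                            config = cohort_config()) {
  stopifnot(inherits(config, "pc_cohort_config"))
  enc <- tables$encounters
  complete <- !is.na(enc$encounter_date) & !is.na(enc$reason_text) &
    nzchar(trimws(as.character(enc$reason_text)))
  flow <- list(encounters_total = nrow(enc),
               encounters_dropped_incomplete = sum(!complete))
  enc <- enc[complete, , drop = FALSE]

  known <- tables$patients$patient_id
  orphan <- !(enc$patient_id %in% known)
  if (any(orphan)) {
    warning(sprintf("skipping %d encounter row(s) with unknown patient_id",
                    sum(orphan)), call. = FALSE)
    enc <- enc[!orphan, , drop = FALSE]
  }

  ev <- merge_symptom_events(
    extract_symptom_events(enc, lexicon),
    detect_biochemical_jaundice(tables$pathology, feat_config),
    detect_new_onset_diabetes(tables$pathology, tables$prescriptions,
                              feat_config, study_start = config$study_start)
  )
  flow$patients_any_symptom_event <- length(unique(ev$patient_id))

  # study window + age band at event date
  pat <- tables$patients
  birth <- pat$birth_date[match(ev$patient_id, pat$patient_id)]
  age_ev <- age_at(birth, ev$event_date)
  keep <- ev$event_date >= config$study_start &
    ev$event_date <= config$study_end &
    age_ev >= config$age_min & age_ev <= config$age_max
  ev <- ev[keep, , drop = FALSE]
  flow$patients_in_window_and_age <- length(unique(ev$patient_id))

  # first C25 diagnosis per patient
  reg <- tables$registry
  c25 <- reg[startsWith(as.character(reg$icd10_code), "C25"), , drop = FALSE]
  c25 <- c25[order(c25$patient_id, c25$diagnosis_date), , drop = FALSE]
  c25 <- c25[!duplicated(c25$patient_id), , drop = FALSE]

  dx_date <- c25$diagnosis_date[match(ev$patient_id, c25$patient_id)]
  first_ev <- stats::ave(as.numeric(ev$event_date), ev$patient_id,
                         FUN = min)
  prior_dx <- !is.na(dx_date) & as.numeric(dx_date) < first_ev
  flow$patients_excluded_prior_cancer <-
    length(unique(ev$patient_id[prior_dx]))
  ev <- ev[!prior_dx, , drop = FALSE]
  flow$final_cohort <- length(unique(ev$patient_id))

  split_ev <- split(ev[, c("event_date", "symptom_code", "source",
                           "provenance")], ev$patient_id)
  pi <- match(names(split_ev), pat$patient_id)
  di <- match(names(split_ev), c25$patient_id)
  timelines <- vector("list", length(split_ev))
  names(timelines) <- names(split_ev)
  for (i in seq_along(split_ev)) {
    evi <- split_ev[[i]]
    rownames(evi) <- NULL
    timelines[[i]] <- structure(list(
      patient_id = names(split_ev)[i],
      sex = pat$sex[pi[i]],
      birth_date = pat$birth_date[pi[i]],
      bmi = pat$bmi[pi[i]],
      seifa = pat$seifa_percentile[pi[i]],
      events = evi,
      diagnosis = if (is.na(di[i])) NULL else
        list(date = c25$diagnosis_date[di[i]],
             icd10 = c25$icd10_code[di[i]])
    ), class = "pc_timeline")
  }
  attr(timelines, "flow") <- flow
  timelines
}

#' Restrict timelines to pre-COVID study entries
#'
#' Keeps timelines whose first event falls on or before
#' `config$precovid_end`: the deterministic subset used by the pre-COVID
#' sensitivity analysis.
#'
#' @param timelines List of `pc_timeline`.
#' @param config A [cohort_config()] with non-NULL `precovid_end`.
#' @return Filtered timeline list.
#' @export
apply_precovid_filter <- function(timelines, config = cohort_config()) {
  stopifnot(!is.null(config$precovid_end))
  keep <- vapply(timelines, function(tl) {
    nrow(tl$events) > 0 && min(tl$events$event_date) <= config$precovid_end
  }, logical(1))
  out <- timelines[keep]
  attr(out, "flow") <- attr(timelines, "flow")
  out
}

#' Evaluate one tool on one patient timeline
#'
#' Implements the study's windowed evaluation: entry at the first event
#' whose code the tool uses; events accumulated over the window
#' `[entry, entry + accumulation_window_days]`; at each event date the tool
#' is re-evaluated on the accumulated qualifying set; collection stops at
#' the earliest of first flag, cancer diagnosis, or window end. The index
#' date is the flag date when flagged, otherwise the last qualifying event
#' before the stop; the outcome is a C25 diagnosis within
#' `[index, index + followup_window_days]` (a diagnosis on the index date
#' itself counts).
#'
#' @param timeline A `pc_timeline`.
#' @param tool A `pc_ruleset` or `pc_riskmodel`.
#' @param config A [cohort_config()].
#' @return List of class `pc_evaluation`: `patient_id`, `tool`, `eligible`,
#'   `entry_date`, `flagged`, `flag_date`, `index_date`,
#'   `outcome_cancer_12m`, `censoring_note`.
#' @export
evaluate_tool <- function(timeline, tool, config = cohort_config()) {
  stopifnot(inherits(timeline, "pc_timeline"), inherits(tool, "pc_tool"))
  codes <- tool_codes(tool)
  ev <- timeline$events
  qual <- ev[ev$symptom_code %in% codes, , drop = FALSE]
  base <- list(patient_id = timeline$patient_id, tool = tool_name(tool),
               eligible = FALSE, entry_date = as.Date(NA), flagged = FALSE,
               flag_date = as.Date(NA), index_date = as.Date(NA),
               outcome_cancer_12m = FALSE, censoring_note = "")
  class(base) <- "pc_evaluation"
  if (nrow(qual) == 0) {
    base$censoring_note <- "no qualifying event for this tool"
    return(base)
  }
  entry <- min(qual$event_date)
  age_entry <- age_at(timeline$birth_date, entry)
  if (!tool_eligible_at(tool, age_entry, timeline$sex)) {
    base$censoring_note <- "ineligible for tool at entry (age/sex)"
    return(base)
  }
  dx <- if (is.null(timeline$diagnosis)) as.Date(NA) else
    timeline$diagnosis$date
  if (!is.na(dx) && dx < entry) {
    # normally excluded by build_timelines; guard for hand-built timelines
    base$censoring_note <- "diagnosis before study entry"
    return(base)
  }
  base$eligible <- TRUE
  base$entry_date <- entry
  window_end <- entry + config$accumulation_window_days
  stop_date <- min(window_end, dx, na.rm = TRUE)

  qual <- qual[qual$event_date >= entry & qual$event_date <= stop_date, ,
               drop = FALSE]
  dates <- sort(unique(qual$event_date))
  flagged <- FALSE
  flag_date <- as.Date(NA)
  for (d in dates) {
    acc <- unique(qual$symptom_code[as.numeric(qual$event_date) <= d])
    if (tool_flag_at(tool, acc, age_entry, timeline$sex,
                     bmi = timeline$bmi, deprivation = timeline$seifa)) {
      flagged <- TRUE
      flag_date <- as.Date(d, origin = "1970-01-01")
      break
    }
  }
  index_date <- if (flagged) flag_date else max(qual$event_date)
  base$flagged <- flagged
  base$flag_date <- flag_date
  base$index_date <- index_date
  if (!is.na(dx)) {
    lag <- as.numeric(dx - index_date)
    base$outcome_cancer_12m <- lag >= 0 && lag <= config$followup_window_days
  }
  base$censoring_note <- if (flagged) "stopped at flag"
    else if (!is.na(dx) && dx <= window_end) "stopped at diagnosis"
    else "stopped at window end"
  base
}

#' Evaluate one tool across a cohort of timelines
#'
#' @param timelines List of `pc_timeline`.
#' @param tool A `pc_ruleset` or `pc_riskmodel`.
#' @param config A [cohort_config()].
#' @return Data frame with one row per timeline (all patients, including
#'   tool-ineligible ones, with `eligible = FALSE`).
#' @export
evaluate_cohort <- function(timelines, tool, config = cohort_config()) {
  rows <- lapply(timelines, function(tl) {
    e <- evaluate_tool(tl, tool, config)
    data.frame(patient_id = e$patient_id, tool = e$tool,
               eligible = e$eligible, entry_date = e$entry_date,
               flagged = e$flagged, flag_date = e$flag_date,
               index_date = e$index_date,
               outcome_cancer_12m = e$outcome_cancer_12m,
               censoring_note = e$censoring_note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
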