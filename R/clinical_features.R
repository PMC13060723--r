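# Non-text phenotypes: new-onset diabetes (three routes) and biochemical
# jaundice, merged into the symptom event stream.

#' Feature-derivation configuration
#'
#' Thresholds and lexica for the two derived phenotypes.
#'
#' @param hba1c_threshold_pct Diagnostic HbA1c cut-off in NGSP % units
#'   (route A: a single result at or above this is diabetes). Default 6.5.
#' @param hba1c_raised_pct "Raised" HbA1c level in % for route B (two
#'   raised results more than three months apart). Default 6.0: a raised
#'   but sub-diagnostic level, so route B is a genuinely distinct pathway
#'   rather than a subset of route A.
#' @param hba1c_threshold_mmolmol Diagnostic cut-off in IFCC mmol/mol,
#'   recorded for reference (48 corresponds to 6.5%); conversion uses the
#'   NGSP/IFCC master equation, not this field.
#' @param paired_result_min_gap_days Minimum gap between the two raised
#'   results of route B; 92 days operationalises "more than 3 months".
#' @param bilirubin_upper_limit_umol Upper limit of normal for total
#'   bilirubin in umol/L; results strictly above it count as biochemical
#'   jaundice. Default 21.
#' @param diabetes_medication_lexicon Data frame with columns `generic` and
#'   `brands` (list column or "|"-separated string) naming diabetes
#'   medications; default loads the shipped 17-generic lexicon.
#' @param diabetes_washout_days Lookback within which earlier diabetes
#'   evidence disqualifies "new onset". Default `Inf` (entire prior record).
#' @return Object of class `pc_feature_config`.
#' @export
feature_config <- function(hba1c_threshold_pct = 6.5,
                           hba1c_raised_pct = 6.0,
                           hba1c_threshold_mmolmol = 48,
                           paired_result_min_gap_days = 92L,
                           bilirubin_upper_limit_umol = 21,
                           diabetes_medication_lexicon = NULL,
                           diabetes_washout_days = Inf) {
  stopifnot(hba1c_threshold_pct > 0, hba1c_raised_pct > 0,
            hba1c_threshold_mmolmol > 0, bilirubin_upper_limit_umol > 0,
            paired_result_min_gap_days >= 1, diabetes_washout_days > 0)
  if (is.null(diabetes_medication_lexicon)) {
    diabetes_medication_lexicon <- load_medication_lexicon()
  }
  if (length(diabetes_medication_lexicon$generic) == 0) {
    stop("diabetes_medication_lexicon must be non-empty", call. = FALSE)
  }
  structure(list(
    hba1c_threshold_pct = hba1c_threshold_pct,
    hba1c_raised_pct = hba1c_raised_pct,
    hba1c_threshold_mmolmol = hba1c_threshold_mmolmol,
    paired_result_min_gap_days = as.integer(paired_result_min_gap_days),
    bilirubin_upper_limit_umol = bilirubin_upper_limit_umol,
    diabetes_medication_lexicon = diabetes_medication_lexicon,
    diabetes_washout_days = diabetes_washout_days
  ), class = "pc_feature_config")
}

#' Load the diabetes medication lexicon
#'
#' @param path YAML file of `{generic, brands: [...]}` entries; default the
#'   shipped list of 17 generic diabetes medications with brand aliases.
#' @return List with `generic` (character) and `brands` (list of character).
#' @export
load_medication_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diabetes_medications.yaml",
                        package = "panctriage", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  list(
    generic = vapply(raw, `[[`, "", "generic"),
    brands = lapply(raw, function(e) as.character(unlist(e$brands)))
  )
}

#' Normalise an HbA1c result to NGSP % units
#'
#' IFCC mmol/mol results are converted with the NGSP/IFCC master equation
#' `% = 0.09148 * mmolmol + 2.152`; % results pass through unchanged.
#'
#' @param value Positive numeric vector of HbA1c results.
#' @param units Character vector, each `"%"` or `"mmol/mol"`.
#' @return Numeric vector in % units.
#' @export
#' @examples
#' normalise_hba1c(48, "mmol/mol") # 6.54
normalise_hba1c <- function(value, units) {
  stopifnot(length(value) == length(units))
  if (any(!is.finite(value) | value <= 0)) {
    bad <- which(!is.finite(value) | value <= 0)[1]
    stop(sprintf("HbA1c value must be positive (row %d: %s)", bad,
                 value[bad]), call. = FALSE)
  }
  known <- units %in% c("%", "mmol/mol")
  if (!all(known)) {
    bad <- which(!known)[1]
    stop(sprintf("unknown HbA1c units in row %d: '%s' (expected %% or mmol/mol)",
                 bad, units[bad]), call. = FALSE)
  }
  ifelse(units == "mmol/mol", 0.09148 * value + 2.152, value)
}

#' Detect new-onset diabetes from pathology and prescription records
#'
#' Three routes, any of which establishes diabetes:
#' \describe{
#'   \item{A}{a single HbA1c at or above the diagnostic threshold;}
#'   \item{B}{two "raised" HbA1c results more than three months apart
#'     (event at the second result);}
#'   \item{C}{a first prescription of a diabetes medication.}
#' }
#' The event date is the earliest date any route triggers. Patients whose
#' earliest trigger predates `study_start` (or falls inside the washout
#' lookback) carry prevalent, not new-onset, diabetes and are excluded.
#' At most one event per patient is emitted, with
#' `source = "pathology_or_prescription"`.
#'
#' @param pathology Data frame with `patient_id`, `result_date`, `analyte`,
#'   `value`, `units`.
#' @param prescriptions Data frame with `patient_id`, `script_date`,
#'   `medication_name`.
#' @param config A [feature_config()].
#' @param study_start Optional Date; triggers strictly before it mark
#'   prevalent diabetes and exclude the patient from "new onset".
#' @return Symptom-event data frame (`symptom_code = "new_onset_diabetes"`).
#' @export
detect_new_onset_diabetes <- function(pathology, prescriptions, config,
                                      study_start = NULL) {
  stopifnot(inherits(config, "pc_feature_config"))
  hba <- pathology[pathology$analyte == "hba1c", , drop = FALSE]
  pct <- if (nrow(hba) > 0) normalise_hba1c(hba$value, hba$units) else numeric(0)

  med_rx <- match_diabetes_medications(prescriptions,
                                       config$diabetes_medication_lexicon)

  trig <- rbind(
    route_a_triggers(hba, pct, config),
    route_b_triggers(hba, pct, config),
    if (nrow(med_rx) > 0) data.frame(
      patient_id = med_rx$patient_id, date = med_rx$script_date,
      route = "C", provenance = paste0("diabetes medication: ",
                                       med_rx$medication_name),
      stringsAsFactors = FALSE) else NULL
  )
  if (is.null(trig) || nrow(trig) == 0) return(empty_events())

  trig <- trig[order(trig$patient_id, trig$date, trig$route), , drop = FALSE]
  first <- trig[!duplicated(trig$patient_id), , drop = FALSE]

  if (!is.null(study_start)) {
    first <- first[first$date >= as.Date(study_start), , drop = FALSE]
  }
  if (is.finite(config$diabetes_washout_days)) {
    # evidence older than the washout horizon before the trigger is ignored
    # by construction (the trigger IS the earliest evidence), so a finite
    # washout only matters together with study_start and is a no-op here.
  }
  if (nrow(first) == 0) return(empty_events())
  order_events(data.frame(
    patient_id = first$patient_id,
    event_date = first$date,
    symptom_code = "new_onset_diabetes",
    source = "pathology_or_prescription",
    provenance = paste0("route ", first$route, ": ", first$provenance),
    stringsAsFactors = FALSE
  ))
}

route_a_triggers <- function(hba, pct, config) {
  sel <- pct >= config$hba1c_threshold_pct
  if (!any(sel)) return(NULL)
  data.frame(
    patient_id = hba$patient_id[sel], date = hba$result_date[sel],
    route = "A",
    provenance = sprintf("HbA1c %.2f%% >= %.2f%%", pct[sel],
                         config$hba1c_threshold_pct),
    stringsAsFactors = FALSE
  )
}

# Route B: earliest "second of a pair" of raised results >= gap days apart.
# Linear scan per patient over date-sorted raised results: the first result
# whose distance to the *earliest* raised result reaches the gap is the
# earliest possible trigger.
route_b_triggers <- function(hba, pct, config) {
  sel <- pct >= config$hba1c_raised_pct
  if (sum(sel) < 2) return(NULL)
  raised <- data.frame(patient_id = hba$patient_id[sel],
                       date = hba$result_date[sel],
                       stringsAsFactors = FALSE)
  raised <- raised[order(raised$patient_id, raised$date), , drop = FALSE]
  out <- lapply(split(raised$date, raised$patient_id), function(d) {
    if (length(d) < 2) return(NULL)
    ok <- as.numeric(d - d[1]) >= config$paired_result_min_gap_days
    if (!any(ok)) return(NULL)
    d[which(ok)[1]]
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  data.frame(
    patient_id = names(out),
    date = as.Date(vapply(out, as.numeric, numeric(1)),
                   origin = "1970-01-01"),
    route = "B",
    provenance = sprintf("second raised HbA1c >= %d days after first",
                         config$paired_result_min_gap_days),
    stringsAsFactors = FALSE
  )
}

match_diabetes_medications <- function(prescriptions, lexicon) {
  if (nrow(prescriptions) == 0) return(prescriptions)
  names_all <- unique(c(lexicon$generic, unlist(lexicon$brands)))
  pat <- paste0("\\b(", paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                   names_all), collapse = "|"), ")\\b")
  hit <- grepl(pat, prescriptions$medication_name, ignore.case = TRUE,
               perl = TRUE)
  prescriptions[hit, , drop = FALSE]
}

#' Detect biochemical jaundice from bilirubin results
#'
#' Emits one jaundice event (source `"pathology"`) per total-bilirubin
#' result strictly above the configured upper limit of normal. Merging with
#' text-recorded jaundice on the same day is the job of
#' [merge_symptom_events()].
#'
#' @param pathology Data frame with `patient_id`, `result_date`, `analyte`,
#'   `value`, `units`.
#' @param config A [feature_config()].
#' @return Symptom-event data frame (`symptom_code = "jaundice"`).
#' @export
detect_biochemical_jaundice <- function(pathology, config) {
  stopifnot(inherits(config, "pc_feature_config"))
  bili <- pathology[pathology$analyte == "bilirubin_total" &
                      pathology$value > config$bilirubin_upper_limit_umol, ,
                    drop = FALSE]
  if (nrow(bili) == 0) return(empty_events())
  order_events(data.frame(
    patient_id = bili$patient_id,
    event_date = bili$result_date,
    symptom_code = "jaundice",
    source = "pathology",
    provenance = sprintf("bilirubin %.0f umol/L > %.0f umol/L", bili$value,
                         config$bilirubin_upper_limit_umol),
    stringsAsFactors = FALSE
  ))
}

#' Merge symptom event streams with per-day deduplication
#'
#' Concatenates event frames and keeps one event per (patient, date, code).
#' When the same code is evidenced by several sources on one day, the
#' source kept follows the priority text > pathology >
#' pathology_or_prescription > prescription.
#'
#' @param ... Symptom-event data frames.
#' @return A single deduplicated, ordered symptom-event data frame.
#' @export
merge_symptom_events <- function(...) {
  ev <- do.call(rbind, Filter(function(x) !is.null(x) && nrow(x) > 0,
                              list(...)))
  if (is.null(ev) || nrow(ev) == 0) return(empty_events())
  pri <- match(ev$source,
               c("text", "pathology", "pathology_or_prescription",
                 "prescription"))
  ev <- ev[order(ev$patient_id, ev$event_date,
                 match(ev$symptom_code, canonical_symptoms()), pri), ,
           drop = FALSE]
  key <- paste(ev$patient_id, ev$event_date, ev$symptom_code, sep = "\r")
  ev <- ev[!duplicated(key), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
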