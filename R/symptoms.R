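# Canonical sign/symptom vocabulary shared by every module.

.SYMPTOM_TABLE <- data.frame(
  code = c(
    "jaundice", "abd_pain", "ep_radiating", "back_pain", "abd_distension",
    "cibh", "constipation", "diarrhoea", "steatorrhoea", "nausea",
    "vomiting", "indigestion", "dysphagia", "appetite_loss", "uwl",
    "fatigue", "pruritus", "new_onset_diabetes", "pancreatitis",
    "gi_bleed", "vte", "new_depression_anxiety", "dark_urine_pale_stools"
  ),
  label = c(
    "Jaundice", "Abd. pain", "EP radiating", "Back pain", "Abd. distension",
    "CIBH", "Constipation", "Diarrhoea", "Steatorrhoea", "Nausea",
    "Vomiting", "Indigestion", "Dysphagia", "Appetite loss", "UWL",
    "Fatigue", "Pruritus/itch", "New-onset diabetes", "Pancreatitis",
    "GI bleed", "VTE", "New depression/anxiety", "Dark urine/pale stools"
  ),
  stringsAsFactors = FALSE
)

#' Canonical sign and symptom codes
#'
#' The 23 standardised signs and symptoms used across the triage tools:
#' everything a tool clause or risk-score covariate may refer to, and
#' everything the free-text mapper or phenotype detectors may emit. The set
#' and its order are fixed; lexicons and rulesets are validated against it.
#'
#' Codes use the field's customary abbreviations (`uwl` = unexpected weight
#' loss, `cibh` = change in bowel habits, `vte` = venous thromboembolism,
#' `ep_radiating` = epigastric pain radiating to the back, `gi_bleed` =
#' gastrointestinal bleed).
#'
#' @return Character vector of length 23, stable order.
#' @seealso [symptom_labels()] for display names.
#' @export
#' @examples
#' canonical_symptoms()
canonical_symptoms <- function() {
  .SYMPTOM_TABLE$code
}

#' Display labels for the canonical symptom codes
#'
#' @return Named character vector mapping code to a human-readable label.
#' @export
symptom_labels <- function() {
  stats::setNames(.SYMPTOM_TABLE$label, .SYMPTOM_TABLE$code)
}

assert_canonical_codes <- function(codes, what = "symptom code") {
  bad <- setdiff(codes, canonical_symptoms())
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown %s(s): %s (must be one of canonical_symptoms())",
      what, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(codes)
}
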