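# Tool engines: a declarative combination-rule engine (shared by eRAT-style
# and QPaC-style tools) and a coefficient-driven sex-specific logistic risk
# score with a probability threshold (QCancer-style).

#' Construct a combination rule set
#'
#' A rule set is a list of clauses; a patient is flagged "high risk" iff at
#' least one clause is satisfied: all its required symptoms co-occur within
#' the accumulation window and its age/sex conditions hold. The behavioural
#' differences between rule-based tools live entirely in this
#' configuration; the evaluator is shared.
#'
#' @param tool_name Character scalar.
#' @param clauses List of lists with `required_symptoms` (non-empty
#'   character vector of canonical codes) and optional `min_age`, `max_age`
#'   (years) and `sex` (`"male"`/`"female"`).
#' @param provenance_note Free-text note on where the clauses came from.
#' @return Object of class `pc_ruleset`.
#' @export
ruleset <- function(tool_name, clauses, provenance_note = "") {
  stopifnot(is.character(tool_name), length(tool_name) == 1,
            is.list(clauses), length(clauses) >= 1)
  clauses <- lapply(clauses, function(cl) {
    req <- as.character(unlist(cl$required_symptoms))
    if (length(req) == 0) stop("clause with empty required_symptoms",
                               call. = FALSE)
    assert_canonical_codes(req, "ruleset code")
    sx <- cl$sex
    if (!is.null(sx) && !sx %in% c("male", "female")) {
      stop(sprintf("clause sex must be male/female, got '%s'", sx),
           call. = FALSE)
    }
    list(required_symptoms = sort(unique(req)),
         min_age = cl$min_age, max_age = cl$max_age, sex = sx)
  })
  keys <- vapply(clauses, function(cl) {
    paste(paste(cl$required_symptoms, collapse = ","),
          cl$min_age %||% "", cl$max_age %||% "", cl$sex %||% "")
  }, character(1))
  if (anyDuplicated(keys)) warning("duplicate clause(s) in ruleset",
                                   call. = FALSE)
  structure(list(tool_name = tool_name, clauses = clauses,
                 provenance_note = provenance_note),
            class = c("pc_ruleset", "pc_tool"))
}

#' Load a rule set from YAML
#'
#' @param path YAML file with `tool_name`, `provenance_note` and `clauses`.
#' @return A [ruleset()].
#' @export
load_ruleset <- function(path) {
  raw <- yaml::read_yaml(path)
  ruleset(raw$tool_name, raw$clauses, raw$provenance_note %||% "")
}

#' Write a rule set to YAML (round-trips with [load_ruleset()])
#' @param rs A `pc_ruleset`.
#' @param path Output path.
#' @export
write_ruleset <- function(rs, path) {
  stopifnot(inherits(rs, "pc_ruleset"))
  clauses <- lapply(rs$clauses, function(cl) {
    out <- list(required_symptoms = cl$required_symptoms)
    for (f in c("min_age", "max_age", "sex")) {
      if (!is.null(cl[[f]])) out[[f]] <- cl[[f]]
    }
    out
  })
  yaml::write_yaml(list(tool_name = rs$tool_name,
                        provenance_note = rs$provenance_note,
                        clauses = clauses), path)
  invisible(path)
}

#' Evaluate a rule set on an accumulated symptom set
#'
#' @param event_codes Character vector (treated as a set) of canonical
#'   symptom codes accumulated in the window.
#' @param age Age in years at evaluation.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param rs A [ruleset()].
#' @return List with `flag` (logical) and `clause` (index of the first
#'   matching clause in file order, or `NA`). Flag status is independent of
#'   clause order; the index is provenance only.
#' @export
rule_flag <- function(event_codes, age, sex, rs) {
  stopifnot(inherits(rs, "pc_ruleset"))
  codes <- unique(as.character(event_codes))
  for (i in seq_along(rs$clauses)) {
    cl <- rs$clauses[[i]]
    if (!all(cl$required_symptoms %in% codes)) next
    if (!is.null(cl$min_age) && age < cl$min_age) next
    if (!is.null(cl$max_age) && age > cl$max_age) next
    if (!is.null(cl$sex) && !identical(sex, cl$sex)) next
    return(list(flag = TRUE, clause = i))
  }
  list(flag = FALSE, clause = NA_integer_)
}

#' Construct a sex-specific logistic risk model
#'
#' The linear predictor for a patient is
#' `intercept + b_age * age/10 + b_bmi * (bmi-25)/5 + b_depr * seifa/100 +
#' sum of symptom-indicator coefficients`, passed through the logistic
#' link; the patient is flagged iff risk strictly exceeds `threshold`.
#' Missing BMI / deprivation are replaced by `default_bmi` /
#' `default_deprivation` ("standard non-risk figures") before evaluation.
#' Coefficient names other than `intercept`, `age_decade`, `bmi_per5` and
#' `deprivation_pct` must be canonical symptom codes.
#'
#' @param model_name Character scalar.
#' @param coefficients List with elements `male` and `female`, each a named
#'   numeric list of coefficients.
#' @param threshold Flagging probability threshold in (0,1]; default 0.02
#'   (1 is allowed as a degenerate never-flag setting).
#' @param age_min,age_max Eligible age range (default 25-89).
#' @param default_bmi,default_deprivation Substitutes for missing BMI
#'   (kg/m2) and deprivation percentile.
#' @param provenance_note Free-text provenance.
#' @return Object of class `pc_riskmodel`.
#' @export
risk_model <- function(model_name, coefficients, threshold = 0.02,
                       age_min = 25, age_max = 89, default_bmi = 25,
                       default_deprivation = 50, provenance_note = "") {
  stopifnot(is.list(coefficients),
            all(c("male", "female") %in% names(coefficients)),
            threshold > 0, threshold <= 1, age_min < age_max)
  special <- c("intercept", "age_decade", "bmi_per5", "deprivation_pct")
  for (sx in c("male", "female")) {
    co <- unlist(coefficients[[sx]])
    if (!all(is.finite(co))) stop("non-finite coefficient", call. = FALSE)
    if (!"intercept" %in% names(co)) {
      stop(sprintf("%s coefficients need an intercept", sx), call. = FALSE)
    }
    assert_canonical_codes(setdiff(names(co), special),
                           "risk-model symptom term")
    coefficients[[sx]] <- co
  }
  structure(list(model_name = model_name, coefficients = coefficients,
                 threshold = threshold, age_min = age_min, age_max = age_max,
                 default_bmi = default_bmi,
                 default_deprivation = default_deprivation,
                 provenance_note = provenance_note),
            class = c("pc_riskmodel", "pc_tool"))
}

#' Load a risk model from a YAML coefficient file
#'
#' @param path YAML file; see `inst/extdata/qcancer_synthetic.yaml` for the
#'   shipped synthetic stand-in.
#' @return A [risk_model()].
#' @export
load_risk_model <- function(path) {
  raw <- yaml::read_yaml(path)
  risk_model(raw$model_name, raw$coefficients,
             threshold = raw$threshold %||% 0.02,
             age_min = raw$age_min %||% 25, age_max = raw$age_max %||% 89,
             default_bmi = raw$default_bmi %||% 25,
             default_deprivation = raw$default_deprivation %||% 50,
             provenance_note = raw$provenance_note %||% "")
}

#' Compute the risk score for one patient
#'
#' @param covariates List with `age` (years), `sex` (`"male"`/`"female"`),
#'   `symptoms` (character vector of codes present in the window), and
#'   optional `bmi`, `deprivation` (NA or NULL means missing).
#' @param model A [risk_model()].
#' @return Probability in (0,1), or `NA_real_` with attribute
#'   `ineligible_reason` when age is outside the model range or sex is
#'   unknown (ineligibility is a marker, not an error).
#' @export
qcancer_risk <- function(covariates, model) {
  stopifnot(inherits(model, "pc_riskmodel"))
  age <- covariates$age
  sex <- covariates$sex
  if (!sex %in% c("male", "female")) {
    return(structure(NA_real_, ineligible_reason = "sex unknown"))
  }
  if (age < model$age_min || age > model$age_max) {
    return(structure(NA_real_, ineligible_reason = sprintf(
      "age %.0f outside model range %d-%d", age, model$age_min,
      model$age_max)))
  }
  co <- model$coefficients[[sex]]
  bmi <- covariates$bmi
  if (is.null(bmi) || is.na(bmi)) bmi <- model$default_bmi
  depr <- covariates$deprivation
  if (is.null(depr) || is.na(depr)) depr <- model$default_deprivation
  lp <- co[["intercept"]]
  if ("age_decade" %in% names(co)) lp <- lp + co[["age_decade"]] * age / 10
  if ("bmi_per5" %in% names(co)) lp <- lp + co[["bmi_per5"]] * (bmi - 25) / 5
  if ("deprivation_pct" %in% names(co)) {
    lp <- lp + co[["deprivation_pct"]] * depr
  }
  sym <- intersect(unique(covariates$symptoms), names(co))
  if (length(sym) > 0) lp <- lp + sum(co[sym])
  stats::plogis(lp)
}

#' Threshold a risk score into a flag
#'
#' @param risk Probability in \[0,1\] (NA means ineligible, never flagged).
#' @param model A [risk_model()].
#' @return Logical: `TRUE` iff `risk` strictly exceeds the threshold.
#' @export
qcancer_flag <- function(risk, model) {
  stopifnot(inherits(model, "pc_riskmodel"))
  !is.na(risk) & risk > model$threshold
}

# ---- shared tool generics used by the cohort evaluator -------------------

#' Symptom codes a tool responds to
#'
#' For a rule set: the union of all clause symptoms. For a risk model: the
#' symptom-indicator coefficient names. These define the "qualifying"
#' events for study entry under that tool.
#'
#' @param tool A `pc_ruleset` or `pc_riskmodel`.
#' @return Character vector of canonical codes.
#' @export
tool_codes <- function(tool) UseMethod("tool_codes")

#' @export
tool_codes.pc_ruleset <- function(tool) {
  sort(unique(unlist(lapply(tool$clauses, `[[`, "required_symptoms"))))
}

#' @export
tool_codes.pc_riskmodel <- function(tool) {
  special <- c("intercept", "age_decade", "bmi_per5", "deprivation_pct")
  sort(unique(c(setdiff(names(tool$coefficients$male), special),
                setdiff(names(tool$coefficients$female), special))))
}

#' Name of a tool
#' @param tool A `pc_ruleset` or `pc_riskmodel`.
#' @return Character scalar.
#' @export
tool_name <- function(tool) {
  if (inherits(tool, "pc_ruleset")) tool$tool_name else tool$model_name
}

# Flag decision on an accumulated window state; shared entry point for the
# incremental cohort evaluator and for the brute-force test oracle.
tool_flag_at <- function(tool, codes, age, sex, bmi = NA, deprivation = NA) {
  if (inherits(tool, "pc_ruleset")) {
    rule_flag(codes, age, sex, tool)$flag
  } else {
    risk <- qcancer_risk(list(age = age, sex = sex, symptoms = codes,
                              bmi = bmi, deprivation = deprivation), tool)
    isTRUE(qcancer_flag(risk, tool))
  }
}

# Age/sex eligibility screen applied at entry (risk models restrict both;
# rule sets keep unknown-sex patients unless a clause requires a sex).
tool_eligible_at <- function(tool, age, sex) {
  if (inherits(tool, "pc_riskmodel")) {
    sex %in% c("male", "female") && age >= tool$age_min && age <= tool$age_max
  } else {
    TRUE
  }
}
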