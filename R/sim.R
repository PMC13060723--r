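# Synthetic linked-EMR generator: patients, free-text encounters, pathology,
# prescriptions and a cancer registry with the marginal structure the
# downstream analysis assumes, so the whole pipeline is testable without
# real data.

#' Default lifetime symptom prevalence map
#'
#' Per symptom: probability of at least one presentation over the study
#' period, conditional on future pancreatic-cancer status. The printed
#' group comparisons anchor several entries (new-onset diabetes 0.293 vs
#' 0.206, jaundice 0.203 vs 0.025, pancreatitis 0.033 vs 0.007, unexpected
#' weight loss 0.077 vs 0.036, back pain 0.255 vs 0.366, fatigue 0.096 vs
#' 0.150, indigestion 0.243 vs 0.285); the remaining values are plausible
#' primary-care fill-ins chosen once and documented in the methods
#' vignette.
#'
#' @return Data frame with columns `symptom`, `p_cancer`, `p_noncancer`.
#' @export
default_symptom_prevalence <- function() {
  x <- rbind(
    c("jaundice",               0.203, 0.025),
    c("abd_pain",               0.320, 0.280),
    c("ep_radiating",           0.005, 0.003),
    c("back_pain",              0.255, 0.366),
    c("abd_distension",         0.045, 0.040),
    c("cibh",                   0.190, 0.175),
    c("constipation",           0.120, 0.130),
    c("diarrhoea",              0.140, 0.150),
    c("steatorrhoea",           0.012, 0.004),
    c("nausea",                 0.105, 0.110),
    c("vomiting",               0.085, 0.090),
    c("indigestion",            0.243, 0.285),
    c("dysphagia",              0.035, 0.030),
    c("appetite_loss",          0.055, 0.030),
    c("uwl",                    0.077, 0.036),
    c("fatigue",                0.096, 0.150),
    c("pruritus",               0.045, 0.040),
    c("new_onset_diabetes",     0.293, 0.206),
    c("pancreatitis",           0.033, 0.007),
    c("gi_bleed",               0.035, 0.030),
    c("vte",                    0.025, 0.015),
    c("new_depression_anxiety", 0.120, 0.140),
    c("dark_urine_pale_stools", 0.012, 0.004)
  )
  data.frame(symptom = x[, 1], p_cancer = as.numeric(x[, 2]),
             p_noncancer = as.numeric(x[, 3]), stringsAsFactors = FALSE)
}

#' Default pre-diagnosis presentation probabilities
#'
#' Per symptom: probability of presenting with it in the 12 months before
#' diagnosis, conditional on being a cancer patient who presented at all in
#' that window (the reported denominator, 324 of 518 = 62.5%, is the
#' presenter rate). Anchored entries: jaundice 0.290, abdominal pain 0.256,
#' change in bowel habits 0.176, new-onset diabetes 0.148.
#'
#' @return Named numeric vector over canonical symptom codes.
#' @export
default_prediagnosis_probs <- function() {
  c(jaundice = 0.290, abd_pain = 0.256, ep_radiating = 0.006,
    back_pain = 0.120, abd_distension = 0.030, cibh = 0.176,
    constipation = 0.060, diarrhoea = 0.060, steatorrhoea = 0.012,
    nausea = 0.070, vomiting = 0.060, indigestion = 0.100,
    dysphagia = 0.020, appetite_loss = 0.050, uwl = 0.090,
    fatigue = 0.060, pruritus = 0.030, new_onset_diabetes = 0.148,
    pancreatitis = 0.030, gi_bleed = 0.020, vte = 0.020,
    new_depression_anxiety = 0.050, dark_urine_pale_stools = 0.010)
}

#' Default free-text lexical variants per symptom
#'
#' At least three spellings/phrasings per symptom, all of which the shipped
#' default lexicon recognises. Decoy (must-not-match) phrasings live in
#' [default_decoy_reasons()].
#'
#' @return Named list of character vectors.
#' @export
default_lexical_variants <- function() {
  list(
    jaundice = c("jaundice", "?jaundice", "yellow sclera", "icterus"),
    abd_pain = c("abdominal pain", "abdo pain", "stomach ache", "tummy pain"),
    ep_radiating = c("epigastric pain radiating to back",
                     "epigastric pain radiating to the back", "ep radiating"),
    back_pain = c("back pain", "backache", "lumbar pain"),
    abd_distension = c("abdominal distension", "bloating",
                       "distended abdomen"),
    cibh = c("change in bowel habit", "altered bowel habit", "CIBH"),
    constipation = c("constipation", "constipated", "hard stools"),
    diarrhoea = c("diarrhoea", "diarrhea", "loose stools"),
    steatorrhoea = c("steatorrhoea", "fatty stools", "greasy stools"),
    nausea = c("nausea", "nauseous", "feeling sick"),
    vomiting = c("vomiting", "vomited", "throwing up"),
    indigestion = c("indigestion", "dyspepsia", "heartburn", "reflux"),
    dysphagia = c("dysphagia", "difficulty swallowing",
                  "trouble swallowing"),
    appetite_loss = c("loss of appetite", "poor appetite", "anorexia"),
    uwl = c("weight loss", "unexplained weight loss", "losing weight",
            "lost 6 kg"),
    fatigue = c("fatigue", "tired all the time", "lethargy", "TATT"),
    pruritus = c("pruritus", "itchy skin", "generalised itch"),
    new_onset_diabetes = c("new onset diabetes", "diabetes new diagnosis",
                           "elevated blood sugar"),
    pancreatitis = c("pancreatitis", "acute pancreatitis", "?pancreatitis"),
    gi_bleed = c("GI bleed", "melaena", "rectal bleeding", "haematemesis"),
    vte = c("DVT", "pulmonary embolism", "VTE", "deep vein thrombosis"),
    new_depression_anxiety = c("depression", "anxiety", "low mood"),
    dark_urine_pale_stools = c("dark urine", "pale stools",
                               "clay coloured stools")
  )
}

#' Default decoy reason-for-encounter texts
#'
#' Near-miss and administrative phrasings that must NOT map to any symptom
#' under the default lexicon: these exercise the exclusion filters.
#'
#' @return Character vector.
#' @export
default_decoy_reasons <- function() {
  c("family history pancreatic cancer", "pancreatic cancer screening discussion",
    "no jaundice", "neonatal jaundice check for baby",
    "weight loss program referral", "intentional weight loss diet",
    "anorexia nervosa review", "chronic depression review",
    "known anxiety medication review", "medication review", "repeat script",
    "flu vaccination", "blood pressure check", "routine check up",
    "certificate request", "test results discussion", "travel advice",
    "feedback on imaging")
}

#' Simulation configuration
#'
#' The stated world of the generator: defaults reproduce the reported
#' cohort structure — ages 40-100 with cancer patients older at
#' presentation (median 74, IQR 65-82 vs 60, IQR 50-72), per-patient
#' symptomatic presentation counts distributed NegBin(size 1, mu 6.5)
#' (quartiles 2/4/9), lifetime symptom prevalence by future cancer status,
#' and pre-diagnosis presentation probabilities concentrated in the 12
#' months before diagnosis for the 62.5% of cancer patients who present in
#' that window.
#'
#' @param n_patients Positive integer.
#' @param cancer_prevalence Fraction of patients receiving a registry C25
#'   record; default 518/185937, the reported symptomatic-cohort rate.
#' @param study_start,study_end Study window (defaults 2007-07-01 /
#'   2021-06-30).
#' @param registry_end Last registry follow-up date (default 2022-06-30).
#' @param age_distribution List with `cancer` and `noncancer`, each
#'   `list(median, iqr = c(lo, hi))` for age at first presentation.
#' @param symptom_prevalence Data frame as [default_symptom_prevalence()].
#' @param prediagnosis_symptom_prob Named vector as
#'   [default_prediagnosis_probs()].
#' @param prediagnosis_presenter_rate P(any qualifying presentation in the
#'   12 months pre-diagnosis | cancer); default 0.625.
#' @param consult_rate List `size`, `mu` for the negative-binomial count of
#'   symptomatic presentations per patient.
#' @param lexical_variants Named list of free-text spellings per symptom.
#' @param decoy_reasons Character vector of must-not-match reason texts.
#' @param lab_params Distribution parameters for bilirubin and HbA1c by
#'   phenotype status, plus `mmolmol_fraction`, the share of HbA1c rows
#'   reported in IFCC units (default 0.5, forcing unit normalisation).
#' @param jaundice_route_mix Probabilities for expressing jaundice as
#'   `text`, `lab` (raised bilirubin) or `both`.
#' @param diabetes_route_mix Probabilities for the three diabetes evidence
#'   routes `hba1c_single`, `hba1c_paired`, `medication`.
#' @param missing_bmi_seifa_rate Probability BMI / SEIFA are missing.
#' @param unknown_sex_rate Probability of unknown sex (default 0.003).
#' @param decoy_encounter_rate Poisson mean of decoy encounters per patient.
#' @param decoy_registry_rate Fraction of non-cancer patients receiving a
#'   non-C25 registry decoy record.
#' @param seed RNG seed; a fixed seed makes output byte-identical.
#' @return Object of class `pc_sim_config`.
#' @export
sim_config <- function(n_patients = 20000,
                       cancer_prevalence = 518 / 185937,
                       study_start = as.Date("2007-07-01"),
                       study_end = as.Date("2021-06-30"),
                       registry_end = as.Date("2022-06-30"),
                       age_distribution = list(
                         cancer = list(median = 74, iqr = c(65, 82)),
                         noncancer = list(median = 60, iqr = c(50, 72))),
                       symptom_prevalence = default_symptom_prevalence(),
                       prediagnosis_symptom_prob = default_prediagnosis_probs(),
                       prediagnosis_presenter_rate = 0.625,
                       consult_rate = list(size = 1, mu = 6.5),
                       lexical_variants = default_lexical_variants(),
                       decoy_reasons = default_decoy_reasons(),
                       lab_params = list(
                         bilirubin_raised = c(meanlog = log(60), sdlog = 0.5),
                         bilirubin_normal = c(min = 4, max = 18),
                         hba1c_diabetic = c(min = 6.6, max = 11),
                         hba1c_raised = c(min = 6.05, max = 6.45),
                         hba1c_normal = c(min = 4.8, max = 5.9),
                         mmolmol_fraction = 0.5),
                       jaundice_route_mix = c(text = 0.5, lab = 0.25,
                                              both = 0.25),
                       diabetes_route_mix = c(hba1c_single = 1 / 3,
                                              hba1c_paired = 1 / 3,
                                              medication = 1 / 3),
                       missing_bmi_seifa_rate = 0.4,
                       unknown_sex_rate = 0.003,
                       decoy_encounter_rate = 1.0,
                       decoy_registry_rate = 0.02,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pc_sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    err("n_patients", "must be a positive integer")
  }
  probs <- c(cancer_prevalence = cfg$cancer_prevalence,
             prediagnosis_presenter_rate = cfg$prediagnosis_presenter_rate,
             missing_bmi_seifa_rate = cfg$missing_bmi_seifa_rate,
             unknown_sex_rate = cfg$unknown_sex_rate,
             decoy_registry_rate = cfg$decoy_registry_rate)
  for (nm in names(probs)) {
    if (!is.finite(probs[[nm]]) || probs[[nm]] < 0 || probs[[nm]] > 1) {
      err(nm, "must be a probability in [0,1]")
    }
  }
  cfg$study_start <- as.Date(cfg$study_start)
  cfg$study_end <- as.Date(cfg$study_end)
  cfg$registry_end <- as.Date(cfg$registry_end)
  if (!cfg$study_start < cfg$study_end) {
    err("study_start", "must precede study_end")
  }
  if (cfg$registry_end < cfg$study_end) {
    err("registry_end", "must not precede study_end")
  }
  sp <- cfg$symptom_prevalence
  if (!all(c("symptom", "p_cancer", "p_noncancer") %in% names(sp))) {
    err("symptom_prevalence", "needs columns symptom/p_cancer/p_noncancer")
  }
  assert_canonical_codes(sp$symptom, "symptom_prevalence code")
  if (any(sp$p_cancer < 0 | sp$p_cancer > 1 | sp$p_noncancer < 0 |
            sp$p_noncancer > 1)) {
    err("symptom_prevalence", "probabilities must lie in [0,1]")
  }
  pre <- cfg$prediagnosis_symptom_prob
  if (any(pre < 0 | pre > 1)) {
    err("prediagnosis_symptom_prob", "probabilities must lie in [0,1]")
  }
  missing_lex <- setdiff(sp$symptom, names(cfg$lexical_variants))
  empty_lex <- names(Filter(function(v) length(v) == 0,
                            cfg$lexical_variants))
  if (length(missing_lex) > 0 || length(empty_lex) > 0) {
    err("lexical_variants", paste("every symptom needs >=1 variant; missing:",
                                  paste(c(missing_lex, empty_lex),
                                        collapse = ", ")))
  }
  cfg
}

# uniform integer dates in [d0, d1]
runif_dates <- function(n, d0, d1) {
  as.Date(as.integer(d0) + floor(stats::runif(n) *
                                   (as.integer(d1) - as.integer(d0) + 1)),
          origin = "1970-01-01")
}

# truncated-normal ages matched to a median/IQR target
sample_ages <- function(n, target, lo = 41, hi = 95) {
  if (n == 0) return(numeric(0))
  mu <- target$median
  sigma <- diff(target$iqr) / (2 * stats::qnorm(0.75))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mu, sigma)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  round(out[seq_len(n)], 1)
}

#' Generate linked synthetic cohort tables
#'
#' Draws the full linked-table world described by a [sim_config()]:
#' patients, free-text encounters, pathology (bilirubin + dual-unit HbA1c),
#' prescriptions, and a registry with C25 records for cancer patients plus
#' non-C25 decoys. Jaundice is expressed as text, raised bilirubin, or both;
#' new-onset diabetes via a single diagnostic HbA1c, a raised pair more
#' than three months apart, or a medication script. Symptomatic encounters
#' of cancer patients concentrate in the 12 months before diagnosis; all
#' output is byte-stable for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List of class `pc_tables` with data frames `patients`,
#'   `encounters`, `pathology`, `prescriptions`, `registry`.
#' @export
generate_cohort_data <- function(config) {
  stopifnot(inherits(config, "pc_sim_config"))
  config <- validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(config$seed))

  n <- as.integer(config$n_patients)
  s0 <- config$study_start
  s1 <- config$study_end
  ids <- sprintf("P%07d", seq_len(n))
  cancer <- stats::runif(n) < config$cancer_prevalence
  u_sex <- stats::runif(n)
  sex <- ifelse(u_sex < config$unknown_sex_rate, "unknown",
                ifelse(stats::runif(n) < 0.44, "male", "female"))
  age <- numeric(n)
  age[cancer] <- sample_ages(sum(cancer), config$age_distribution$cancer)
  age[!cancer] <- sample_ages(sum(!cancer), config$age_distribution$noncancer)

  dx_date <- rep(as.Date(NA), n)
  dx_date[cancer] <- runif_dates(sum(cancer), s0 + 380, config$registry_end)

  # ---- symptom presence ---------------------------------------------------
  sp <- config$symptom_prevalence
  k <- nrow(sp)
  pre_probs <- config$prediagnosis_symptom_prob[sp$symptom]
  pre_probs[is.na(pre_probs)] <- 0
  presenter <- cancer & stats::runif(n) < config$prediagnosis_presenter_rate

  # prediagnosis draws (presenters only), guaranteed non-empty
  prediag <- matrix(FALSE, n, k, dimnames = list(NULL, sp$symptom))
  idx_pres <- which(presenter)
  if (length(idx_pres) > 0) {
    prediag[idx_pres, ] <- matrix(
      stats::runif(length(idx_pres) * k) < rep(pre_probs,
                                               each = length(idx_pres)),
      ncol = k)
    none <- idx_pres[rowSums(prediag[idx_pres, , drop = FALSE]) == 0]
    if (length(none) > 0) {
      forced <- sample.int(k, length(none), replace = TRUE,
                           prob = pmax(pre_probs, 1e-6))
      prediag[cbind(none, forced)] <- TRUE
    }
  }

  # background presence: calibrated so the union hits the lifetime target
  pre_marg <- config$prediagnosis_presenter_rate * pre_probs
  q_cancer <- ifelse(sp$p_cancer > pre_marg,
                     1 - (1 - sp$p_cancer) / (1 - pre_marg), 0)
  presence <- matrix(FALSE, n, k, dimnames = list(NULL, sp$symptom))
  u <- matrix(stats::runif(n * k), n, k)
  presence[cancer, ] <- u[cancer, , drop = FALSE] <
    rep(q_cancer, each = sum(cancer))
  presence[!cancer, ] <- u[!cancer, , drop = FALSE] <
    rep(sp$p_noncancer, each = sum(!cancer))
  background <- presence
  presence <- presence | prediag

  # ---- event pairs (patient x present symptom) ----------------------------
  pairs <- which(presence, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  p_row <- pairs[, 1]
  p_sym <- sp$symptom[pairs[, 2]]
  p_prediag <- prediag[pairs]
  p_backgr <- background[pairs]

  npresent <- tabulate(p_row, nbins = n)
  total <- stats::rnbinom(n, size = config$consult_rate$size,
                          mu = config$consult_rate$mu)
  total <- pmin(pmax(total, npresent), 60L)
  total[npresent == 0] <- 0L

  # one event per pair, extras spread uniformly over the patient's pairs;
  # the one-off diabetes phenotype never receives extras
  k_pair <- rep(1L, nrow(pairs))
  extra <- total - npresent
  first_pair <- c(0L, cumsum(npresent))[seq_len(n)]
  donors <- which(extra > 0 & npresent > 0)
  if (length(donors) > 0) {
    slot_pat <- rep(donors, extra[donors])
    slot_pair <- first_pair[slot_pat] +
      floor(stats::runif(length(slot_pat)) * npresent[slot_pat]) + 1L
    add <- tabulate(slot_pair, nbins = nrow(pairs))
    k_pair <- k_pair + add
  }
  k_pair[p_sym == "new_onset_diabetes"] <- 1L

  # per-pair date window
  pat_dx <- dx_date[p_row]
  w0 <- rep(as.integer(s0), nrow(pairs))
  w1 <- rep(as.integer(s1), nrow(pairs))
  has_dx <- !is.na(pat_dx)
  in_pre <- has_dx & p_prediag
  w0[in_pre] <- pmax(as.integer(s0), as.integer(pat_dx[in_pre]) - 365L)
  w1[in_pre] <- pmin(as.integer(s1), as.integer(pat_dx[in_pre]))
  back_only <- has_dx & !p_prediag
  w1[back_only] <- pmin(as.integer(s1), as.integer(pat_dx[back_only]) - 366L)
  w0 <- pmin(w0, w1)  # degenerate windows collapse to a point

  ev_pair <- rep(seq_len(nrow(pairs)), k_pair)
  ev_date <- as.Date(w0[ev_pair] +
                       floor(stats::runif(length(ev_pair)) *
                               (w1[ev_pair] - w0[ev_pair] + 1L)),
                     origin = "1970-01-01")
  ev_row <- p_row[ev_pair]
  ev_sym <- p_sym[ev_pair]

  # ---- expression routes --------------------------------------------------
  jmix <- config$jaundice_route_mix / sum(config$jaundice_route_mix)
  dmix <- config$diabetes_route_mix / sum(config$diabetes_route_mix)
  pair_route <- rep("text", nrow(pairs))
  jp <- p_sym == "jaundice"
  pair_route[jp] <- sample(names(jmix), sum(jp), replace = TRUE, prob = jmix)
  dp <- p_sym == "new_onset_diabetes"
  pair_route[dp] <- sample(names(dmix), sum(dp), replace = TRUE, prob = dmix)
  ev_route <- pair_route[ev_pair]

  # ---- encounters ---------------------------------------------------------
  text_ev <- !(ev_sym == "new_onset_diabetes") & ev_route != "lab"
  variants <- config$lexical_variants
  reason <- character(sum(text_ev))
  t_sym <- ev_sym[text_ev]
  for (s in unique(t_sym)) {
    sel <- t_sym == s
    reason[sel] <- sample(variants[[s]], sum(sel), replace = TRUE)
  }
  multi <- stats::runif(sum(text_ev)) < 0.2
  reason[multi] <- paste(reason[multi],
                         sample(config$decoy_reasons, sum(multi),
                                replace = TRUE), sep = "; ")
  enc <- data.frame(patient_id = ids[ev_row[text_ev]],
                    encounter_date = ev_date[text_ev],
                    reason_text = reason, stringsAsFactors = FALSE)
  n_decoy <- stats::rpois(n, config$decoy_encounter_rate)
  if (sum(n_decoy) > 0) {
    d_row <- rep(seq_len(n), n_decoy)
    enc <- rbind(enc, data.frame(
      patient_id = ids[d_row],
      encounter_date = runif_dates(length(d_row), s0, s1),
      reason_text = sample(config$decoy_reasons, length(d_row),
                           replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # ---- pathology ----------------------------------------------------------
  lp <- config$lab_params
  bili_ev <- ev_sym == "jaundice" & ev_route %in% c("lab", "both")
  path <- data.frame(patient_id = character(0),
                     result_date = as.Date(character(0)),
                     analyte = character(0), value = numeric(0),
                     units = character(0), stringsAsFactors = FALSE)
  if (any(bili_ev)) {
    val <- pmin(pmax(stats::rlnorm(sum(bili_ev), lp$bilirubin_raised["meanlog"],
                                   lp$bilirubin_raised["sdlog"]), 25), 400)
    path <- rbind(path, data.frame(
      patient_id = ids[ev_row[bili_ev]], result_date = ev_date[bili_ev],
      analyte = "bilirubin_total", value = round(val, 0), units = "umol/L",
      stringsAsFactors = FALSE))
  }
  norm_bili <- which(stats::runif(n) < 0.05)
  if (length(norm_bili) > 0) {
    path <- rbind(path, data.frame(
      patient_id = ids[norm_bili],
      result_date = runif_dates(length(norm_bili), s0, s1),
      analyte = "bilirubin_total",
      value = round(stats::runif(length(norm_bili), lp$bilirubin_normal["min"],
                                 lp$bilirubin_normal["max"]), 0),
      units = "umol/L", stringsAsFactors = FALSE))
  }

  emit_hba1c <- function(pid, date, value_pct) {
    mm <- stats::runif(length(pid)) < lp$mmolmol_fraction
    data.frame(
      patient_id = pid, result_date = date,
      analyte = "hba1c",
      value = ifelse(mm, round((value_pct - 2.152) / 0.09148, 0),
                     round(value_pct, 1)),
      units = ifelse(mm, "mmol/mol", "%"), stringsAsFactors = FALSE)
  }
  dia_ev <- ev_sym == "new_onset_diabetes"
  dia_route <- ev_route[dia_ev]
  dia_pid <- ids[ev_row[dia_ev]]
  dia_date <- ev_date[dia_ev]
  ra <- dia_route == "hba1c_single"
  if (any(ra)) {
    path <- rbind(path, emit_hba1c(
      dia_pid[ra], dia_date[ra],
      stats::runif(sum(ra), lp$hba1c_diabetic["min"],
                   lp$hba1c_diabetic["max"])))
  }
  rb <- dia_route == "hba1c_paired"
  if (any(rb)) {
    gap <- 92L + floor(stats::runif(sum(rb)) * 250)
    d2 <- dia_date[rb]
    d1 <- pmax(as.integer(s0), as.integer(d2) - gap)
    # a pair squeezed below the minimum gap degrades to the single route
    squeezed <- (as.integer(d2) - d1) < 92L
    raised_val <- function(m) stats::runif(m, lp$hba1c_raised["min"],
                                           lp$hba1c_raised["max"])
    if (any(!squeezed)) {
      path <- rbind(path,
                    emit_hba1c(dia_pid[rb][!squeezed],
                               as.Date(d1[!squeezed], origin = "1970-01-01"),
                               raised_val(sum(!squeezed))),
                    emit_hba1c(dia_pid[rb][!squeezed], d2[!squeezed],
                               raised_val(sum(!squeezed))))
    }
    if (any(squeezed)) {
      path <- rbind(path, emit_hba1c(
        dia_pid[rb][squeezed], d2[squeezed],
        stats::runif(sum(squeezed), lp$hba1c_diabetic["min"],
                     lp$hba1c_diabetic["max"])))
    }
  }
  norm_hba <- which(stats::runif(n) < 0.10 & !presence[, "new_onset_diabetes"])
  if (length(norm_hba) > 0) {
    path <- rbind(path, emit_hba1c(
      ids[norm_hba], runif_dates(length(norm_hba), s0, s1),
      stats::runif(length(norm_hba), lp$hba1c_normal["min"],
                   lp$hba1c_normal["max"])))
  }

  # ---- prescriptions ------------------------------------------------------
  med_lex <- load_medication_lexicon()
  med_names <- c(med_lex$generic, unlist(med_lex$brands))
  rx <- data.frame(patient_id = character(0),
                   script_date = as.Date(character(0)),
                   medication_name = character(0), stringsAsFactors = FALSE)
  rc <- dia_route == "medication"
  if (any(rc)) {
    rx <- rbind(rx, data.frame(
      patient_id = dia_pid[rc], script_date = dia_date[rc],
      medication_name = sample(med_names, sum(rc), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  decoy_meds <- c("atorvastatin", "perindopril", "salbutamol inhaler",
                  "esomeprazole", "cephalexin", "levothyroxine")
  decoy_rx <- which(stats::runif(n) < 0.2)
  if (length(decoy_rx) > 0) {
    rx <- rbind(rx, data.frame(
      patient_id = ids[decoy_rx],
      script_date = runif_dates(length(decoy_rx), s0, s1),
      medication_name = sample(decoy_meds, length(decoy_rx), replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # ---- registry -----------------------------------------------------------
  reg <- data.frame(patient_id = character(0),
                    diagnosis_date = as.Date(character(0)),
                    icd10_code = character(0), stringsAsFactors = FALSE)
  if (any(cancer)) {
    reg <- rbind(reg, data.frame(
      patient_id = ids[cancer], diagnosis_date = dx_date[cancer],
      icd10_code = sample(c("C25.0", "C25.1", "C25.2", "C25.9"), sum(cancer),
                          replace = TRUE),
      stringsAsFactors = FALSE))
  }
  decoy_reg <- which(!cancer & stats::runif(n) < config$decoy_registry_rate)
  if (length(decoy_reg) > 0) {
    reg <- rbind(reg, data.frame(
      patient_id = ids[decoy_reg],
      diagnosis_date = runif_dates(length(decoy_reg), s0 + 380,
                                   config$registry_end),
      icd10_code = sample(c("C18.9", "C50.9", "C61", "D12.6"),
                          length(decoy_reg), replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # ---- patients -----------------------------------------------------------
  # birth anchored at the first symptomatic event so age-at-first-
  # presentation matches the sampled age exactly
  anchor <- rep(as.integer(s0) + 2000L, n)
  if (length(ev_row) > 0) {
    first_ev <- tapply(as.integer(ev_date), ev_row, min)
    anchor[as.integer(names(first_ev))] <- as.integer(first_ev)
  }
  birth <- as.Date(anchor - floor(age * 365.25) -
                     floor(stats::runif(n) * 180), origin = "1970-01-01")
  bmi <- round(stats::rnorm(n, 27, 5), 1)
  bmi[bmi < 15] <- 15
  bmi[stats::runif(n) < config$missing_bmi_seifa_rate] <- NA
  seifa <- sample.int(100, n, replace = TRUE)
  seifa[stats::runif(n) < config$missing_bmi_seifa_rate] <- NA
  patients <- data.frame(patient_id = ids, sex = sex, birth_date = birth,
                         bmi = bmi, seifa_percentile = seifa,
                         stringsAsFactors = FALSE)

  sort_tbl <- function(df, date_col) {
    df <- df[order(df$patient_id, df[[date_col]],
                   seq_len(nrow(df))), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  structure(list(
    patients = patients,
    encounters = sort_tbl(enc, "encounter_date"),
    pathology = sort_tbl(path, "result_date"),
    prescriptions = sort_tbl(rx, "script_date"),
    registry = sort_tbl(reg, "diagnosis_date")
  ), class = "pc_tables")
}

#' @export
print.pc_tables <- function(x, ...) {
  cat("<pc_tables>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %7d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
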