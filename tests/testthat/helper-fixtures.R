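# Shared fixtures: hand-built timelines, tiny rulesets, random-case
# generators. Everything is built in code at test time.

mk_events <- function(dates, codes) {
  data.frame(event_date = as.Date(dates), symptom_code = codes,
             source = "text", provenance = "", stringsAsFactors = FALSE)
}

mk_timeline <- function(dates, codes, dx = NULL, sex = "female",
                        birth = "1950-01-01", id = "T1", bmi = NA_real_,
                        seifa = NA_integer_) {
  timeline(id, sex, as.Date(birth), mk_events(dates, codes),
           diagnosis = if (is.null(dx)) NULL else
             list(date = as.Date(dx), icd10 = "C25.9"),
           bmi = bmi, seifa = seifa)
}

# two-clause test ruleset: jaundice alone, or weight loss + abdominal pain
tiny_ruleset <- function() {
  ruleset("tiny", list(
    list(required_symptoms = "jaundice", min_age = 40),
    list(required_symptoms = c("uwl", "abd_pain"))
  ))
}

# random small timeline for evaluator property tests
random_timeline <- function(codes_pool = c("jaundice", "uwl", "abd_pain",
                                           "back_pain", "nausea")) {
  n_ev <- sample(1:6, 1)
  dates <- as.Date("2012-06-01") + sample(-200:500, n_ev, replace = TRUE)
  codes <- sample(codes_pool, n_ev, replace = TRUE)
  dx <- if (runif(1) < 0.4) as.Date("2012-06-01") + sample(-100:800, 1)
        else NULL
  mk_timeline(dates, codes, dx = dx,
              sex = sample(c("male", "female"), 1),
              birth = as.Date("1945-01-01") + sample(0:7000, 1))
}

random_ruleset <- function(codes_pool = c("jaundice", "uwl", "abd_pain",
                                          "back_pain", "nausea")) {
  n_cl <- sample(1:4, 1)
  suppressWarnings(ruleset("random", lapply(seq_len(n_cl), function(i) {
    list(required_symptoms = sample(codes_pool, sample(1:3, 1)),
         min_age = if (runif(1) < 0.3) 40 else NULL)
  })))  # duplicate clauses are fine for property tests
}

# five-patient worked micro-example with hand-computed expectations
micro_timelines <- function() {
  list(
    A = mk_timeline("2010-01-10", "jaundice", dx = "2010-03-01", id = "A"),
    B = mk_timeline(c("2012-05-01", "2012-08-01"), c("abd_pain", "uwl"),
                    id = "B"),
    C = mk_timeline("2013-01-01", "back_pain", id = "C"),
    D = mk_timeline("2014-01-01", "uwl", dx = "2015-06-01", id = "D"),
    E = mk_timeline("2011-02-01", "nausea", id = "E")
  )
}

# hand-labelled reason strings: gold standard for the default lexicon,
# written before looking at extractor output
gold_reasons <- function() {
  lab <- function(text, ...) list(text = text, codes = c(...))
  list(
    lab("jaundice", "jaundice"),
    lab("?jaundice", "jaundice"),
    lab("yellow sclera", "jaundice"),
    lab("icterus noted", "jaundice"),
    lab("no jaundice"),
    lab("neonatal jaundice check"),
    lab("abdominal pain", "abd_pain"),
    lab("abdo pain", "abd_pain"),
    lab("stomach ache", "abd_pain"),
    lab("epigastric pain", "abd_pain"),
    lab("epigastric pain radiating to back", "ep_radiating"),
    lab("ep radiating", "ep_radiating"),
    lab("back pain", "back_pain"),
    lab("backache", "back_pain"),
    lab("feedback on results"),
    lab("bloating", "abd_distension"),
    lab("distended abdomen", "abd_distension"),
    lab("change in bowel habit", "cibh"),
    lab("CIBH", "cibh"),
    lab("constipated", "constipation"),
    lab("hard stools", "constipation"),
    lab("diarrhoea", "diarrhoea"),
    lab("loose stools", "diarrhoea"),
    lab("steatorrhoea", "steatorrhoea"),
    lab("fatty stools", "steatorrhoea"),
    lab("nausea and dizziness", "nausea"),
    lab("feeling sick", "nausea"),
    lab("vomiting", "vomiting"),
    lab("haematemesis", "gi_bleed"),
    lab("indigestion", "indigestion"),
    lab("heartburn", "indigestion"),
    lab("dysphagia", "dysphagia"),
    lab("difficulty swallowing", "dysphagia"),
    lab("loss of appetite", "appetite_loss"),
    lab("anorexia", "appetite_loss"),
    lab("anorexia nervosa review"),
    lab("weight loss", "uwl"),
    lab("lost 6 kg", "uwl"),
    lab("weight loss program referral"),
    lab("intentional weight loss diet"),
    lab("tired all the time", "fatigue"),
    lab("lethargy", "fatigue"),
    lab("itchy skin", "pruritus"),
    lab("pruritus", "pruritus"),
    lab("pancreatitis", "pancreatitis"),
    lab("family history of pancreatitis"),
    lab("melaena", "gi_bleed"),
    lab("DVT", "vte"),
    lab("pulmonary embolism", "vte"),
    lab("low mood", "new_depression_anxiety"),
    lab("chronic depression review"),
    lab("dark urine", "dark_urine_pale_stools"),
    lab("pale stools", "dark_urine_pale_stools"),
    lab("routine script renewal"),
    lab("blood pressure check")
  )
}

# minimal hand-built linked tables for cohort tests
mk_tables <- function(patients = NULL, encounters = NULL, pathology = NULL,
                      prescriptions = NULL, registry = NULL) {
  empty_pat <- data.frame(patient_id = character(0), sex = character(0),
                          birth_date = as.Date(character(0)),
                          bmi = numeric(0), seifa_percentile = integer(0))
  empty_enc <- data.frame(patient_id = character(0),
                          encounter_date = as.Date(character(0)),
                          reason_text = character(0))
  empty_path <- data.frame(patient_id = character(0),
                           result_date = as.Date(character(0)),
                           analyte = character(0), value = numeric(0),
                           units = character(0))
  empty_rx <- data.frame(patient_id = character(0),
                         script_date = as.Date(character(0)),
                         medication_name = character(0))
  empty_reg <- data.frame(patient_id = character(0),
                          diagnosis_date = as.Date(character(0)),
                          icd10_code = character(0))
  structure(list(patients = patients %||% empty_pat,
                 encounters = encounters %||% empty_enc,
                 pathology = pathology %||% empty_path,
                 prescriptions = prescriptions %||% empty_rx,
                 registry = registry %||% empty_reg),
            class = "pc_tables")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sort_codes <- function(codes) {
  if (length(codes) == 0) return(character(0))
  codes[order(match(codes, canonical_symptoms()))]
}
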