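Package: panctriage
Title: External Validation of Symptom-Based Pancreatic Cancer Triage Tools
Version: 0.1.0
Authors@R:
    person("Patron", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for externally validating
    symptom-based pancreatic cancer risk assessment tools (eRAT, QCancer
    and QPaC) against linked primary-care and cancer-registry data.
    Provides free-text symptom extraction with a configurable regex
    lexicon, derivation of clinical phenotypes (new-onset diabetes,
    biochemical jaundice), windowed retrospective cohort construction
    with index dates, declarative rule and regression tool engines,
    diagnostic accuracy statistics with exact binomial confidence
    intervals, and a synthetic linked electronic-medical-record
    generator so the whole pipeline is testable without access to
    real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
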