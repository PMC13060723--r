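# SYNTHETIC coefficient file for the sex-specific logistic risk model
# engine (QCancer-style). These coefficients are NOT the published model:
# they are a stand-in with the published model's shape (sex-specific
# intercept, age, BMI and deprivation terms plus symptom indicators, no
# jaundice term) so the engine can be exercised and tested. Load the real
# published coefficients for a faithful validation.
model_name: QCancer-synthetic
threshold: 0.02
age_min: 25
age_max: 89
default_bmi: 25
default_deprivation: 50
provenance_note: >-
  Synthetic stand-in coefficients; magnitudes chosen to give baseline
  12-month risks of order 1e-4 at age 60 rising steeply with age and
  alarm-symptom count. Jaundice is deliberately absent, matching the
  published pancreatic model's covariate set.
coefficients:
  male:
    intercept: -10.2
    age_decade: 0.52
    bmi_per5: -0.05
    deprivation_pct: 0.002
    abd_pain: 1.0
    uwl: 1.4
    new_onset_diabetes: 0.9
    appetite_loss: 1.0
    dysphagia: 0.6
    indigestion: 0.45
    cibh: 0.5
    constipation: 0.3
    vomiting: 0.5
    back_pain: 0.25
    vte: 0.8
    gi_bleed: 0.6
  female:
    intercept: -10.4
    age_decade: 0.54
    bmi_per5: -0.05
    deprivation_pct: 0.002
    abd_pain: 1.0
    uwl: 1.35
    new_onset_diabetes: 0.85
    appetite_loss: 1.05
    dysphagia: 0.6
    indigestion: 0.45
    cibh: 0.5
    constipation: 0.3
    vomiting: 0.5
    back_pain: 0.25
    vte: 0.8
    gi_bleed: 0.6
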