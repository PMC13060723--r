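# eRAT-style combination rule set. ILLUSTRATIVE DEFAULT, synthetic: the
# published high-risk combination table is externally published and should
# replace these clauses for a faithful validation. Any single clause whose
# required symptoms all co-occur within the accumulation window (and whose
# age/sex conditions hold) flags the patient as high risk.
tool_name: eRAT
provenance_note: >-
  Illustrative default clauses reconstructed from the tool's public
  description (jaundice alone; pairwise combinations anchored on weight
  loss and abdominal pain). Replace with the published combination table.
clauses:
  - {required_symptoms: [jaundice], min_age: 40}
  - {required_symptoms: [uwl, abd_pain], min_age: 40}
  - {required_symptoms: [uwl, new_onset_diabetes], min_age: 40}
  - {required_symptoms: [uwl, back_pain], min_age: 40}
  - {required_symptoms: [uwl, cibh], min_age: 40}
  - {required_symptoms: [uwl, appetite_loss], min_age: 40}
  - {required_symptoms: [abd_pain, new_onset_diabetes], min_age: 40}
  - {required_symptoms: [abd_pain, steatorrhoea], min_age: 40}
  - {required_symptoms: [ep_radiating], min_age: 40}
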