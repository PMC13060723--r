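# QPaC-style urgent-referral combination rule set. ILLUSTRATIVE DEFAULT,
# synthetic: the published decision-support criteria should replace these
# clauses for a faithful validation. The tool's "persistent symptom"
# qualifier is not representable in encounter data and is intentionally
# not modelled.
tool_name: QPaC
provenance_note: >-
  Illustrative default clauses reconstructed from the tool's public
  description (jaundice alone; steatorrhoea or pancreatitis alone; broader
  pairwise combinations than eRAT, without the persistence qualifier).
clauses:
  - {required_symptoms: [jaundice], min_age: 40}
  - {required_symptoms: [steatorrhoea], min_age: 40}
  - {required_symptoms: [pancreatitis], min_age: 40}
  - {required_symptoms: [uwl, abd_pain], min_age: 40}
  - {required_symptoms: [uwl, new_onset_diabetes], min_age: 40}
  - {required_symptoms: [uwl, nausea], min_age: 40}
  - {required_symptoms: [uwl, indigestion], min_age: 40}
  - {required_symptoms: [abd_pain, new_onset_diabetes], min_age: 50}
  - {required_symptoms: [abd_pain, cibh], min_age: 50}
  - {required_symptoms: [dark_urine_pale_stools], min_age: 40}
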