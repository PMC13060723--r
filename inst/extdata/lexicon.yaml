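# Default symptom lexicon: case-insensitive regex include/exclude filters
# applied per reason segment. Illustrative configuration — replace with a
# locally validated filter list for production use. new_onset_diabetes is
# deliberately absent: that phenotype is derived from pathology and
# prescription data, never from encounter text.
- code: jaundice
  include: ["jaundice[d]?", "icter(us|ic)", "yellow (skin|sclera|eyes)"]
  exclude: ["neonatal", "newborn", "no jaundice", "jaundice (excluded|ruled out)"]
- code: abd_pain
  include: ["abdominal pain", "abdo?\\.? pain", "stomach (pain|ache)s?",
            "tummy (pain|ache)s?", "epigastric pain"]
  exclude: ["radiat"]
- code: ep_radiating
  include: ["epigastric pain radiat\\w+( to)?( the)? back", "ep radiating"]
  exclude: []
- code: back_pain
  include: ["back ?pain", "backache", "pain in( the)?( lower)? back", "lumbar pain"]
  exclude: ["feedback"]
- code: abd_distension
  include: ["abdominal distension", "abdo?\\.? distension", "distended abdomen",
            "bloat\\w*"]
  exclude: []
- code: cibh
  include: ["changes? in bowel habits?", "altered bowel habits?", "\\bcibh\\b",
            "bowel habit change"]
  exclude: []
- code: constipation
  include: ["constipat(ed|ion)", "hard stools?"]
  exclude: []
- code: diarrhoea
  include: ["diarrh?o?ea", "loose (stools?|bowels?)", "watery stools?"]
  exclude: []
- code: steatorrhoea
  include: ["steator?rh?o?ea", "fatty stools?", "greasy stools?"]
  exclude: []
- code: nausea
  include: ["nause(a|ous|ated)", "feeling sick"]
  exclude: ["no nausea"]
- code: vomiting
  include: ["vomit\\w*", "emesis", "throwing up"]
  exclude: ["haematemesis", "hematemesis"]
- code: indigestion
  include: ["indigestion", "dyspepsia", "heart ?burn", "reflux"]
  exclude: []
- code: dysphagia
  include: ["dysphagia", "(difficulty|trouble|pain) (in )?swallowing"]
  exclude: []
- code: appetite_loss
  include: ["loss of appetite", "appetite loss", "poor appetite", "anorexia",
            "not eating"]
  exclude: ["anorexia nervosa"]
- code: uwl
  include: ["weight ?loss", "losing weight", "lost \\d+ ?kg", "\\buwl\\b"]
  exclude: ["intentional", "weight loss (program(me)?|clinic|diet|surgery)",
            "trying to lose"]
- code: fatigue
  include: ["fatigue[d]?", "\\btired(ness)?( all the time)?", "letharg(y|ic)",
            "\\btatt\\b"]
  exclude: []
- code: pruritus
  include: ["pruritus", "\\bitch(y|ing|iness)?\\b", "generalised itch"]
  exclude: []
- code: pancreatitis
  include: ["pancreatitis"]
  exclude: ["(history|hx) of", "previous", "family history"]
- code: gi_bleed
  include: ["gi bleed\\w*", "gastrointestinal bleed\\w*", "mel(a)?ena",
            "rectal bleed\\w*", "h(a)?ematemesis", "blood in stools?"]
  exclude: []
- code: vte
  include: ["\\bvte\\b", "\\bdvt\\b", "deep vein thrombosis",
            "pulmonary embol\\w*", "venous thromboembol\\w*"]
  exclude: []
- code: new_depression_anxiety
  include: ["\\bdepress(ion|ed)", "anxiety", "anxious", "low mood"]
  exclude: ["chronic", "long[- ]standing", "known", "medication review",
            "repeat (script|prescription)"]
- code: dark_urine_pale_stools
  include: ["dark urine", "pale stools?", "clay.colou?red stools?"]
  exclude: []
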