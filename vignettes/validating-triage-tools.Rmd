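---
title: "Validating symptom-based pancreatic cancer triage tools on linked EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating symptom-based pancreatic cancer triage tools on linked EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panctriage)
```

## The problem

Symptom-based triage tools assign primary-care patients a pancreatic-cancer
risk from their recorded presentations. Two tool families are supported:

* **Combination rules** (eRAT-like, QPaC-like): a list of clauses, each a
  set of signs/symptoms plus optional age/sex conditions; any satisfied
  clause confers "high risk".
* **Regression scores** (QCancer-like): sex-specific logistic models over
  age, BMI, deprivation and symptom indicators, thresholded at a risk
  probability (default, flag iff risk > 0.02, strict, following the
  published ">2%" phrasing).

External validation asks: among patients flagged by a tool, how many truly
develop pancreatic cancer within 12 months? Answering this from electronic
medical records requires reconstructing the tool's inputs from messy
free-text and laboratory data, and respecting the temporal design — entry,
accumulation, stopping, index date, follow-up — exactly.

## The evaluation model

For each tool, a patient enters at their first event whose code the tool
uses. Events then accumulate within `[entry, entry + 365]` days. At each
event date the tool is re-evaluated on the accumulated set (same-day events
are processed as one batch, so a same-day combination can flag). Collection
stops at the earliest of: first flag, registry C25 diagnosis, or window
end. The index date is the flag date if flagged, else the last qualifying
event before the stop. The outcome is a C25 diagnosis with
`0 <= (diagnosis - index) <= 365` days.

Two boundary decisions deserve note:

* **A diagnosis on the index date counts as an outcome.** Because
  collection stops *at* diagnosis, the index routinely coincides with the
  diagnosis date (jaundice, then diagnosis within days). An exclusive lower
  bound would silently discard exactly the cases the tools exist to catch.
* **Age is fixed at entry** for clause conditions and the risk score; a
  12-month window rarely crosses an age threshold, and a single evaluation
  age keeps the incremental and brute-force evaluators comparable.

One evaluation per patient per tool, anchored at the first entry — a
patient cannot re-qualify later, mirroring a single index date per person.

The incremental evaluator's contract is checked against an independent
brute-force oracle (enumerate every event-date cut, test the tool on the
cut's accumulated set) over 1000 randomised small timelines, plus a
translation-equivariance property (shifting all dates by *k* days shifts
entry/flag/index dates by exactly *k*).

## Phenotypes that are not free text

Two tool inputs cannot come from encounter text alone.

**New-onset diabetes** is established by the earliest of three routes:
(A) a single HbA1c at/above the diagnostic threshold (default 6.5% NGSP /
48 mmol/mol); (B) two "raised" results more than three months apart
(operationalised as >= 92 days; event at the second result); (C) a first
prescription of one of 17 configurable diabetes medications (generic or
brand). Any qualifying evidence before the study start marks prevalent
diabetes and disqualifies "new onset". Results reported in IFCC mmol/mol
are converted by the NGSP/IFCC master equation (% = 0.09148 × mmol/mol +
2.152) before thresholding.

The "raised" level of route B defaults to 6.0%, *below* the 6.5%
diagnostic threshold. This is a deliberate departure from treating the two
levels as equal: if raised == diagnostic, any raised result already fires
route A at the first result, so route B could never contribute an event and
would be untestable dead logic. A sub-diagnostic raised band makes route B
a real clinical pathway (persistent pre-diabetic elevation), and both
levels stay configurable.

**Biochemical jaundice** is a total bilirubin strictly above the upper
limit of normal (default 21 µmol/L, configurable). This limit is the lever
that most changes the jaundice PPV: widening the jaundice definition with
laboratory results adds presenters with lower cancer risk. Text-recorded
and biochemical jaundice on the same day deduplicate to one event (text
provenance wins).

Route B is verified against an O(n²) all-pairs oracle on random laboratory
timelines, and both detectors satisfy threshold antitonicity (raising any
threshold never adds events) as randomised property tests.

## Free-text symptom mapping

Reason-for-encounter strings are split into segments (default delimiters
`; , |` and newline) and each segment is matched against a regex lexicon:
a symptom code is emitted iff at least one include pattern matches and no
exclude pattern matches *the same segment*. Segment scoping matters:
"no jaundice; back pain" must veto jaundice without suppressing back pain.
Uncertainty prefixes ("?jaundice") count as present — a queried symptom is
still the reason for the encounter — while negations and incidental
mentions ("family history", "weight loss program") are handled by exclusion
patterns. There is no NLP negation parser; the method is regex-level by
design.

The shipped lexicon (`inst/extdata/lexicon.yaml`) is an illustrative,
replaceable configuration: tests pin its behaviour to a hand-labelled
55-string gold fixture written before the extractor ran, not to any
externally published filter list. The mapper itself is guaranteed monotone:
adding an include pattern never removes an event, adding an exclude pattern
never adds one. New-onset diabetes is intentionally absent from the text
lexicon — it is derived from pathology and prescriptions only.

## The synthetic world

`sim_config()` states the generator's world once; the defaults are the
conditions the validation setting reports, and they are not tuned
afterwards:

| Quantity | Default | Source of the value |
|---|---|---|
| cancer prevalence in the symptomatic cohort | 518/185 937 ≈ 0.28% | reported cohort |
| age at first presentation | median 74 (IQR 65–82) cancer; 60 (50–72) non-cancer | reported descriptives |
| symptomatic presentations per patient | NegBin(size 1, µ 6.5) → quartiles 2/4/9 | fitted to reported median 4 (IQR 2–9) |
| lifetime symptom presence | e.g. jaundice 20.3% vs 2.5%, new-onset diabetes 29.3% vs 20.6% | reported group comparisons |
| pre-diagnosis presenters | 62.5% of cancer patients | reported 324/518 |
| pre-diagnosis symptom probabilities | e.g. jaundice 29.0%, abdominal pain 25.6% | reported, denominator = presenters |
| unknown sex | 0.3% | reported |
| HbA1c unit dialects | 50% NGSP %, 50% IFCC mmol/mol | forces unit normalisation |

Where the setting reports no value (the remaining symptom prevalences,
missing-BMI rate 40%, jaundice route mixture 50/25/25 text/lab/both,
diabetes route mixture 1/3 each, decoy encounter rate Poisson(1)), a
plausible primary-care figure was chosen once and documented here.

Generative structure, and what it does **not** claim: symptom presence is
independent Bernoulli per symptom given cancer status, because only
marginal proportions are reported — inter-symptom correlation in real data
is a known omission. Pre-diagnosis presentation is modelled conditional on
being a presenter (matching the reported denominators), and background
presence is calibrated so the union reproduces the lifetime marginals,
which is what the 4-binomial-SE calibration test checks at n = 20 000.
Consultation seasonality, COVID-era effects, practice clustering and
linkage error are out of scope. A green calibration test therefore
establishes that the pipeline recovers configured marginal structure from
realistic messy encodings (lexical variants, decoy text, dual-unit labs,
three diabetes routes) — not that the generator is a faithful model of any
real population.

Every draw happens under one seed with the caller's RNG state restored;
two runs with the same config are byte-identical down to the written CSVs,
which the determinism test asserts at 20 000 patients.

## Numerical choices

* **Proportion CIs: Clopper–Pearson** (beta-quantile form) by default.
  The deciding observation: for 102/7432 the exact interval reproduces the
  published two-decimal bounds (1.12–1.66%), where the Wilson lower bound
  differs in the second decimal. Wilson and Wald remain available.
* **Likelihood-ratio CIs: log method**, SE(log LR+) =
  √(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)); undefined margins return
  undefined-statistic markers rather than errors, as do zero denominators
  in any proportion statistic.
* **χ² without continuity correction** (configurable) on 2×2 presence
  tables; unknown-sex patients are excluded from the sex comparison.
  **Mann–Whitney U** uses the tie-corrected normal approximation. Both are
  delegated to R's stats primitives and cross-checked against a 10⁵-shuffle
  permutation oracle in the tests.
* **Coverage**: Clopper–Pearson coverage is verified empirically (≥95%
  over 2000 binomial draws at p = 0.013, the cohort's outcome scale).
* **Ties and batches**: same-day events evaluate as one batch; the index
  date for an unflagged patient is the last qualifying event ≤ the stop
  time; duplicate (patient, date, code) events collapse with source
  priority text > pathology > prescription.

## Known limitations

* The shipped rulesets and risk coefficients are stand-ins with the right
  *shape*; conclusions about the real tools require loading their published
  tables. Engine correctness, not fidelity of defaults, is what the test
  suite establishes.
* Sensitivity/specificity denominators are tool-specific (each tool sees
  only patients with its own qualifying symptoms, plus its age/sex
  restrictions); outputs carry `n_eligible` per tool so the denominator is
  explicit.
* The text mapper is regex-only: misspellings, clinical codes and
  narrative-note symptoms are out of scope, as they are for the regex-level
  method it implements.
* With realistic prevalence (~0.3%) a 20 000-patient simulation yields few
  cancer cases; tool-level estimates on synthetic data carry wide CIs.
  This is faithful to the setting rather than a defect, but it means the
  synthetic world demonstrates mechanics, not power.
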