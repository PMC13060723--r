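# panctriage

Pancreatic cancer is usually diagnosed late; symptom-based triage tools
(eRAT, QCancer, QPaC) promise to flag the primary-care patients whose
presentations warrant urgent investigation. Whether those tools keep their
promised predictive value outside the data they were built on is an
external-validation question, and answering it from electronic medical
records takes a long chain of unglamorous steps: free-text symptom
extraction, laboratory/prescription phenotyping, windowed cohort
construction with index dates, tool evaluation, and diagnostic-accuracy
statistics with exact confidence intervals.

`panctriage` packages that chain as tested, reusable R components for
epidemiologists validating triage rules against linked primary-care +
cancer-registry data. Because real linked data cannot be shipped, the
package includes a first-class synthetic linked-EMR generator that emulates
the statistical structure such validations assume, so every stage is
exercised end to end without any patient data.

## What it computes

For each patient, the first qualifying sign or symptom marks study entry.
Symptoms accumulate for up to 12 months; collection stops at the earliest
of a "high-risk" flag, a registry pancreatic-cancer diagnosis (ICD-10 C25),
or window end. The index date is the flag date (if flagged) or the last
qualifying symptom; a diagnosis within 12 months of the index date is the
outcome. From the resulting 2×2 table the package reports, per tool:

- sensitivity, specificity, PPV, NPV, accuracy — each with an exact
  Clopper–Pearson 95% CI (Wilson/Wald available),
- LR+ = sens/(1−spec) and LR− = (1−sens)/spec with log-method CIs,
- per-symptom PPVs, prevalence tables by cancer status, and cohort
  descriptives (Pearson χ², Mann–Whitney U).

Tools are pure configuration: combination-rule tools are YAML clause lists
evaluated by one shared engine; QCancer-style tools are sex-specific
logistic coefficient files with a probability threshold (default, flag iff
risk > 2%) and default substitution for missing BMI/deprivation. The
shipped rulesets and coefficients are labelled illustrative/synthetic
stand-ins — swap in the published tables for a faithful validation.

## Worked example

```r
library(panctriage)

res <- run_pipeline(run_config(
  out_dir = "demo",
  sim  = sim_config(n_patients = 20000, seed = 1),
  seed = 1))

read.csv("demo/tool_confusion.csv")
#>     tool tp  fp fn    tn n_eligible
#>     eRAT  6 618 15 13910      14549
#>     QPaC 10 846  8 13543      14407
#>  QCancer  3  20  9 16410      16442

subset(res$stats, tool == "eRAT")
#>  tool       statistic estimate ci_low ci_high          method
#>  eRAT sensitivity_pct    28.57  11.28   52.18 clopper-pearson
#>  eRAT specificity_pct    95.75  95.41   96.07 clopper-pearson
#>  eRAT         ppv_pct     0.96   0.35    2.08 clopper-pearson
#>  eRAT         npv_pct    99.89  99.82   99.94 clopper-pearson
#>  eRAT         lr_plus     6.72   3.40   13.27      log-method
#>  eRAT        lr_minus     0.75   0.57    0.98      log-method
#>  eRAT    accuracy_pct    95.65  95.31   95.97 clopper-pearson
```

Reading: of 14 549 patients with an eRAT-qualifying presentation, 624 were
flagged high risk and 6 of those were diagnosed with pancreatic cancer
within 12 months of their index date (PPV 0.96%, 95% CI 0.35–2.08) — the
familiar picture for these tools in low-prevalence symptomatic populations:
high NPV and specificity, low PPV. Per-symptom PPVs land in the same range
(`demo/per_symptom_ppv.csv` puts jaundice at 1.35%, 95% CI 0.54–2.76, from
7/519 presenters under the default synthetic world).

The bundle directory also contains `cohort_flow.json` (exclusion cascade),
`table1.csv`, `prevalence.csv` (lifetime and pre-diagnosis symptom
proportions) and `provenance.json`. The same pipeline runs from tables on
disk (`run_config(input_dir = ...)`) in place of the simulator, and a CLI
wraps each stage:

```sh
Rscript inst/cli/panctriage.R simulate --n 20000 --seed 1 --out tables/
Rscript inst/cli/panctriage.R run --in tables/ --out report/
```

## Package layout

- `R/sim.R` — synthetic linked-EMR generator (`sim_config`,
  `generate_cohort_data`)
- `R/symptom_mapping.R`, `R/lexicon.R` — regex lexicon and free-text
  extraction
- `R/clinical_features.R` — new-onset diabetes (three routes) and
  biochemical jaundice
- `R/cohort.R` — timelines, entry/window/stopping/index logic
- `R/tool_engines.R` — rule engine and logistic risk-score engine
- `R/stats.R` — confusion matrices, CIs, likelihood ratios, group tests
- `R/pipeline.R`, `R/cli.R` — orchestration, report bundle, CLI
- `inst/extdata/` — default lexicon, medication list, illustrative
  rulesets, synthetic coefficients (all YAML, all replaceable)
- `vignettes/validating-triage-tools.Rmd` — the methods vignette
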