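# akivalid

Validation of ICD-10 acute kidney injury (AKI) coding in hospital
administrative data against a creatinine-based KDIGO reference standard.

## What it is for

Administrative databases such as the Japanese Diagnosis Procedure
Combination (DPC) system record AKI as ICD-10 N17.x complication codes.
Studies that rely on those codes need to know how well they track real,
laboratory-confirmed AKI. When daily creatinine results are available (via
SS-MIX-style laboratory feeds), the coding can be validated against the
KDIGO serum-creatinine criteria. `akivalid` implements that validation for
surgical cohorts as a tested, reusable pipeline:

* **KDIGO phenotyping** — baseline creatinine as the mean of outpatient
  values 7–365 days before surgery (with latest-outpatient and
  latest-inpatient variants), daily-maximum reduction, and staged
  adjudication: a ≥ 1.5-fold rise from baseline (stage by peak ratio band
  1.5–1.9 / 2.0–2.9 / ≥ 3.0), a ≥ 0.3 mg/dL rise within a rolling 48-hour
  window, renal replacement therapy, and the ≥ 4.0 mg/dL stage-3 rule;
  baseline eGFR by the Japanese equation
  194·SCr^−1.094·age^−0.287 (× 0.739 for women).
* **Eligibility cascade** — adults, surgery within 7 days of admission,
  baseline and follow-up creatinine available, no transplant, no
  maintenance dialysis, baseline SCr < 4 mg/dL and eGFR ≥ 15 — with an
  attrition (flowchart) report.
* **Diagnostic accuracy** — sensitivity, specificity, PPV, NPV, LR+, LR−
  and diagnostic odds ratio with 95% CIs (Clopper–Pearson exact for
  proportions, log-method for ratios), overall, restricted to KDIGO stages
  2–3, by subgroup (eGFR stratum, admission type, cardiovascular vs other
  surgery) and for an expanded code set (N17.x + N19 + N99.0).
* **Synthetic cohorts** — a seeded generator producing DPC-style tables
  with known ground truth, built so the phenotyper provably recovers the
  latent AKI status and stage of every patient.
* **Pipeline** — one config + one seed → attrition table, adjudications,
  a validation report and a hash-bearing manifest; plus the four standard
  sensitivity analyses.

## Worked example

The headline use: accuracy metrics from a 2×2 table of coding against the
KDIGO reference (here the reconstructed overall table of a 7,374-patient
surgical validation cohort: 27 true positives, 8 false positives, 636
false negatives, 6,703 true negatives):

```r
library(akivalid)
compute_metrics(contingency_2x2(tp = 27, fp = 8, fn = 636, tn = 6703))
#> Diagnostic test accuracy (n = 7374, prevalence 9.0%)
#>   2x2: tp = 27, fp = 8, fn = 636, tn = 6703
#>   sensitivity: 4.1% (2.7-5.9%)
#>   specificity: 99.9% (99.8-99.9%)
#>   ppv:         77.1% (59.9-89.6%)
#>   npv:         91.3% (90.7-92.0%)
#>   lr_plus:     34.2 (15.6-74.9)
#>   lr_minus:    0.96 (0.95-0.98)
#>   dor:         35.6 (16.1-78.6)
```

Reading: coding misses most KDIGO AKI (sensitivity 4.1%) but a recorded
code almost always indicates real AKI (specificity 99.9%, PPV 77%,
LR+ ≫ 10), so codes are usable to *identify* AKI cases but not to *count*
them.

The same numbers can be produced end to end — simulate, screen, phenotype,
validate — from a synthetic cohort:

```r
cfg <- run_config(cohort = cohort_config(n_patients = 2000), seed = 20260927)
run <- run_pipeline(cfg)
#> pipeline: read 2000, excluded 0, eligible 2000, reference-positive 170, index-positive 12
run$report[1:2, c("row", "n_reference", "n_index", "sensitivity", "specificity", "ppv")]
#>         row n_reference n_index       sensitivity         specificity                ppv
#>     overall         170      12  5.9% (2.9-10.6%) 99.9% (99.6-100.0%) 83.3% (51.6-97.9%)
#>  stages_2_3          51      12 19.6% (9.8-33.1%) 99.9% (99.6-100.0%) 83.3% (51.6-97.9%)
```

With an `out_dir`, the run also writes `attrition.csv`,
`adjudications.csv`, `report.csv`, `report.json` and a `manifest.json` with
MD5 hashes of every artifact; `run_sensitivity_suite()` adds the 7-day
detection window, the two alternative baseline definitions and the expanded
code set as separate reports. A thin command-line wrapper with
`simulate` / `phenotype` / `eligibility` / `validate` / `run-all` /
`sensitivity-suite` subcommands lives at `inst/cli/akival`.

See the vignette (`vignettes/aki-coding-validation.Rmd`) for the model,
the generator's guarantees and all tuning parameters.

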