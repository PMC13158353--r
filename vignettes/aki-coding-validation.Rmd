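---
title: "Validating administrative AKI coding against the KDIGO creatinine criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating administrative AKI coding against the KDIGO creatinine criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akivalid)
```

## The problem

Hospital administrative databases record acute kidney injury (AKI) as an
ICD-10 diagnosis code (the N17 block), assigned by clinicians at discharge.
Research that selects or adjudicates AKI from those codes inherits whatever
misclassification the coding process introduces. When daily laboratory data
are available alongside the claims — as in Japanese DPC hospitals that also
run the SS-MIX standardized record exchange — the codes can be validated
against a computable reference standard: the KDIGO serum-creatinine
criteria applied to the measured creatinine trajectory around surgery.

`akivalid` implements that validation end to end for surgical cohorts:

1. a **KDIGO phenotyping engine** that estimates a pre-surgery baseline
   creatinine and adjudicates AKI presence and stage from post-operative
   values;
2. an **eligibility cascade** reproducing the usual inclusion/exclusion
   criteria of such studies, with an attrition report;
3. a **diagnostic accuracy estimator** (`dta()`) for the 2x2 table of
   coding against the laboratory reference, with exact and log-method
   confidence intervals, stage-restricted references, subgroups and
   code-set variants;
4. a **synthetic cohort generator** with known ground truth, so the whole
   pipeline is testable without access to hospital data; and
5. a **pipeline layer** that runs everything reproducibly from one seed and
   one configuration, including four standard sensitivity analyses.

## The reference standard

A patient's baseline creatinine is, by default, the arithmetic mean of
outpatient values drawn 7–365 days before the index surgery
(`compute_baseline()`, method `mean_outpatient_7_365`). The window start of
7 days keeps acute peri-operative values out of the baseline; the 365-day
limit keeps it current. Two alternatives used as sensitivity analyses are
the most recent outpatient value in the same window and the most recent
inpatient value before surgery.

Baseline eGFR uses the three-variable Japanese equation

$$\mathrm{eGFR} = 194 \cdot \mathrm{SCr}^{-1.094} \cdot \mathrm{age}^{-0.287}
\;(\times\, 0.739 \text{ for women}), \quad \mathrm{mL/min/1.73\,m^2},$$

and eGFR strata (≥60.0, 30.0–59.9, 15.0–29.9) are left-closed so the
printed band labels partition the axis exactly.

Adjudication (`adjudicate_aki()`) first reduces same-day repeats to the
daily maximum, then applies, over a detection window starting at surgery:

* **relative rise** — any value ≥ 1.5 × baseline; the *stage* is the band
  of the peak ratio: 1 for [1.5, 2.0), 2 for [2.0, 3.0), 3 for ≥ 3.0.
  Half-open bands match the conventional "1.5–1.9 / 2.0–2.9 / ≥3.0"
  labels without gaps;
* **absolute rise** — any value exceeding by ≥ 0.3 mg/dL the minimum
  creatinine observed in the preceding 2 calendar days (stage 1 unless the
  ratio band says more);
* **renal replacement therapy** — a first dialysis procedure (haemodialysis
  J038 or peritoneal dialysis J042) on or after the surgery day: stage 3;
* **creatinine ≥ 4.0 mg/dL** — stage 3, by default only when a rise rule
  or RRT also fires (`scr4_requires_aki = TRUE`).

Two operational points are genuinely open in the usual prose definition of
the absolute rule, and both are configuration switches with a documented
default:

* *"within 2 days"* is read as a **rolling 48-hour window**: each
  post-operative value is compared against the minimum of all values in the
  preceding two calendar days — post-operative values, pre-surgery
  inpatient values when present, and otherwise the baseline estimate
  treated as if observed on the surgery day. This is the KDIGO-faithful
  reading; the stricter variant that compares each value against the
  baseline alone is available as `absolute_rule = "vs_baseline"`.
* a lone value ≥ 4.0 mg/dL without any qualifying rise is **not** counted
  as stage 3 by default (`scr4_requires_aki = TRUE`), matching the KDIGO
  requirement that the absolute-level criterion applies to patients who
  first meet the AKI definition. Because the eligibility cascade already
  removes baselines ≥ 4 mg/dL, the switch rarely matters either way.

When both the absolute and the relative rule fire on the same (first)
trigger day, the recorded trigger is the higher-stage one, and
`relative_rise` on equal stage. A case with no in-window creatinine and no
RRT is returned as *not evaluable* (negative-by-absence), so eligibility —
not the adjudicator — decides to drop it. The main-analysis window runs
through discharge (creatinine is extracted through the discharge date); the
first sensitivity analysis restricts detection to 7 days after surgery,
inclusive.

Thresholds are compared with a 1e-9 tolerance so that decimal creatinine
values sitting exactly on a threshold (1.3 vs 1.0) are not lost to binary
floating-point representation.

## Eligibility

`apply_eligibility()` retains hospitalizations that satisfy all of: age
≥ 18; index surgery (the first of multiple surgeries) at most 7 days after
admission; at least one outpatient creatinine 7–365 days before surgery; at
least one creatinine within 2 days after surgery; no renal-transplant
marker (ICD-10 Z94.0 or procedure K780/K780-2); no maintenance dialysis
(J038/J042 with an end-stage renal disease comorbidity at admission, or any
dialysis on/before the surgery day); and baseline creatinine < 4 mg/dL with
baseline eGFR ≥ 15. ICD-10 matching is prefix-based after dot-stripping,
since dialects differ on dots ("N17" matches N17, N17.0 and N170). The
ESRD comorbidity code set is an argument (default N18.5/N18.6/N18.0): fee
schedules do not pin down a single code.

Every criterion is record-intrinsic, so the final cohort is independent of
the ordering; the attrition table's attribution follows the order above,
and the two missing-creatinine rows can be merged for flowchart-style
reporting (`group_missing = TRUE`). Each hospitalization is an independent
analysis unit: repeat admissions of one patient count as separate cases,
mirroring source data in which identifiers are per-hospitalization.

## Accuracy statistics

`dta()` / `compute_metrics()` report sensitivity, specificity, PPV, NPV,
LR+, LR− and the diagnostic odds ratio with 95% intervals:

* **proportions** use Clopper–Pearson exact (beta-quantile) intervals.
  The method choice matters at the third decimal: for 27/663 the exact
  interval is 2.7–5.9% where Wilson's score interval gives 2.8–5.9%;
* **likelihood ratios** use the log method with
  $SE(\ln LR^+) = \sqrt{1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)}$ and the
  analogous form for LR−;
* **DOR** uses Woolf's log method,
  $SE(\ln DOR) = \sqrt{1/tp + 1/fp + 1/fn + 1/tn}$. This interval is
  approximate, and alternative software choices give slightly different
  bounds; the point estimate, not the interval method, is what the
  package treats as canonical.

Zero cells make ratio estimates infinite or undefined; these are flagged,
never raised as errors, and the ratio *intervals* are then computed from
cells with a 0.5 continuity correction (Haldane–Anscombe), flagged
`continuity_corrected`. That keeps subgroup rows with zero false positives
(common in small strata with very specific coding) reportable.

The index test is positive when any complication-role diagnosis matches
the code set: the N17 block by default, or N17 plus N19 (unspecified renal
failure) and N99.0 (postprocedural renal failure) in the expanded set used
by the fourth sensitivity analysis. Comorbidity-at-admission codes never
count: the validation targets complications arising in hospital.
Stage-restricted references (`stage_restricted_reference()`) keep the full
cohort denominator and simply move lower-stage AKI into the
reference-negative group.

Report rounding follows the conventional precision of coding-validation
tables: percentages and LR+/DOR to one decimal, LR− to two.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* the analysis needs — an
outpatient baseline series, a pre-surgery inpatient value, a post-operative
inpatient trajectory, procedure codes, and role-tagged ICD-10 codes — with
a latent truth record per hospitalization. Defaults describe a plausible
elective surgical population: 46.8% male; ages truncated-normal (mean 61.8,
SD 15.9, range 18–95); eGFR strata 73.7/24.5/1.9%; 1.5% emergent
admissions; 9.6% cardiovascular surgery; ~9% overall AKI incidence with a
76/12/12% stage mix; stage-dependent coding sensitivity (1.2%, 7.3%, 19.5%
for stages 1/2/3 — about 4% overall and 13% for stages 2–3, rising with
severity as coding behaviour does); coding specificity 99.88%; and 62% of
stage-3 cases reaching stage 3 through post-operative dialysis. AKI
incidence is configured per surgery-by-admission cell
(cardiovascular/planned 23.8%, cardiovascular/emergent 50%,
other/planned 7.05%, other/emergent 28.8%); the cell values were chosen to
reproduce the marginal incidences above under independent assignment of
surgery and admission type, with the sparsely observed
cardiovascular-emergent cell set to 50%.

The generator's central guarantee is *exact recoverability*: against the
mean-outpatient baseline, every non-AKI trajectory stays below both rules
and every AKI trajectory meets exactly its assigned stage's rule, each with
a configurable relative margin (`noise_margin`, default 0.1). Concretely,
non-AKI peak ratios stay ≤ 1.5(1−m) and rolling 48-hour rises ≤
0.3(1−m) mg/dL; stage-by-ratio cases draw their peak ratio inside
[band·(1+m), band-top]; stage-1 cases alternate between the absolute
(+0.3·(1+m) mg/dL within 48 h at a peak ratio ≤ 1.5(1−m)) and the relative
mechanism so both branches of the definition are exercised. The outpatient
noise is mean-centred, so the mean-outpatient baseline equals the latent
baseline exactly. Two boundary interactions are resolved in favour of KDIGO
consistency rather than the nominal assignment:

* the sampled stratum eGFR is floored so the implied baseline creatinine
  stays below 3.5 mg/dL (otherwise young patients in the 15.0–29.9 stratum
  would be generated only to be excluded for baseline ≥ 4 mg/dL);
* when a baseline is high enough that any qualifying rise would cross
  4.0 mg/dL, a nominal stage-1/2 assignment is escalated to the stage the
  KDIGO rules would actually award (stage 1 falls back to the absolute
  mechanism where possible; stage 2 escalates to 3). The realized stage in
  the truth table is always the escalated one, so truth and phenotype agree
  by construction.

Surgery occurs 1–3 days after admission so that an admission-day inpatient
creatinine exists and the latest-inpatient baseline variant is defined for
every patient. About 20% of patients get a same-day duplicate measurement
below the daily value, exercising the daily-maximum rule.

What the generator does **not** emulate: renal physiology (no drug
nephrotoxicity, no autocorrelated day-to-day noise beyond threshold
placement), seasonal or secular coding drift, inter-hospital variation, and
any correlation between coding behaviour and anything except true stage.
Tests passing on synthetic data therefore demonstrate the *software* is
faithful to the stated rules, not that the rules are clinically complete.

`inject_exclusions()` converts randomly chosen patients into carriers of a
named exclusion (minors, late surgery, transplant, maintenance dialysis,
high baseline, missing baseline/follow-up), recording the intended reason
in the truth table so attrition attribution is testable.

## Reproducibility and problem sizes

`run_pipeline()` takes one configuration (R object or YAML) and one seed;
identical inputs give byte-identical output files, and the run manifest
records settings, row counts and MD5 hashes of every artifact.
`run_sensitivity_suite()` adds the four standard variants (7-day window,
latest-outpatient baseline, latest-inpatient baseline, expanded code set),
each changing exactly one lever.

The test suite checks adjudication against a brute-force oracle
(enumerating all value pairs at most two days apart) on 1,300 random
fixtures, interval coverage on 2,000 binomial replicates per success
probability, and full-pipeline parameter recovery on synthetic cohorts of
5,000 and 7,374 hospitalizations — sizes at which three binomial standard
errors separate configured from pathological behaviour while the whole
suite stays fast.

## Limitations

* Urine-output KDIGO criteria are out of scope (the motivating data carry
  no urine output), as are paediatric and non-Japanese eGFR equations.
* The DOR confidence interval method (Woolf) is one defensible choice among
  several; treat DOR intervals as approximate.
* The eligibility cascade assumes per-hospitalization identifiers and does
  not link patients across hospitalizations.
* The package consumes the documented CSV dialect only; it does not parse
  DPC claim files or SS-MIX HL7 messages.
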