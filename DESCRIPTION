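Package: akivalid
Title: Validation of Administrative Acute Kidney Injury Coding Against
    KDIGO Creatinine Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate ICD-10 acute kidney injury (AKI) diagnosis
    coding in hospital administrative data against a creatinine-based
    KDIGO reference standard. Provides a KDIGO phenotyping engine
    (baseline creatinine estimation, daily-maximum reduction, staged
    adjudication with rolling 48-hour absolute-rise and relative-rise
    rules, renal replacement therapy), a surgical-cohort eligibility
    cascade with attrition reporting, a diagnostic test accuracy
    estimator (sensitivity, specificity, predictive values, likelihood
    ratios, diagnostic odds ratio with exact and log-method confidence
    intervals), stage-restricted and subgroup analyses, a seeded
    synthetic electronic-health-record cohort generator with known
    ground truth, and a reproducible end-to-end pipeline with
    sensitivity-analysis variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
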