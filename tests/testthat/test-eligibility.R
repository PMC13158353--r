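test_that("index surgery is the first of multiple surgeries", {
  rec <- function(days) data.frame(hospitalization_id = "H1",
                                   surgery_days = days,
                                   stringsAsFactors = FALSE)
  expect_equal(select_index_surgery(rec("3;9")), 3)
  expect_equal(select_index_surgery(rec("5")), 5)
  expect_equal(select_index_surgery(rec("2;2")), 2)
  expect_error(select_index_surgery(rec("")), "surgical")
})

test_that("ICD-10 prefix matching is dot- and case-insensitive", {
  expect_equal(icd10_match(c("N17", "N17.0", "N170", "n17.9", "N18.5", "Z940"),
                           "N17"),
               c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(icd10_match("Z94.0", "Z940"))
  expect_false(icd10_match("N99", "N99.0"))
})

test_that("each exclusion criterion removes the intended patient", {
  ok <- make_patient("OK")
  cases <- list(
    age_under_18 = make_patient("X", age = 17),
    surgery_after_day_7 = make_patient("X", surgery_day = 8),
    no_baseline_creatinine = local({
      p <- make_patient("X")
      p$measurements <- p$measurements[p$measurements$setting != "outpatient", ]
      p
    }),
    no_followup_creatinine = local({
      p <- make_patient("X")
      p$measurements <- p$measurements[p$measurements$setting != "inpatient", ]
      p
    }),
    renal_transplant = local({
      p <- make_patient("X")
      p$diagnoses <- data.frame(hospitalization_id = "X", icd10 = "Z94.0",
                                role = "comorbidity_at_admission",
                                stringsAsFactors = FALSE)
      p
    }),
    maintenance_dialysis = local({
      p <- make_patient("X")
      p$procedures <- data.frame(hospitalization_id = "X", code = "J038",
                                 day = 1L, stringsAsFactors = FALSE)
      p  # dialysis on/before surgery day 2
    }),
    high_baseline_scr_or_low_egfr = local({
      # baseline eGFR 14 -> excluded even though creatinine < 4
      p <- make_patient("X", age = 70,
                        baseline = scr_for_egfr(14, 70, "male"))
      p
    }))
  for (crit in names(cases)) {
    res <- apply_eligibility(bind_patients(ok, cases[[crit]]))
    expect_equal(res$cohort$hospitalizations$hospitalization_id, "OK")
    att <- as.data.frame(res$attrition)
    expect_equal(att$n_excluded[att$criterion == crit], 1L,
                 label = paste("exclusion at", crit))
    expect_equal(names(res$excluded_ids), crit)
  }
})

test_that("dialysis exclusion needs ESRD at admission or pre-surgery timing", {
  # post-surgery dialysis without ESRD: this is stage-3 AKI, not exclusion
  p <- make_patient("X", surgery_day = 2)
  p$procedures <- data.frame(hospitalization_id = "X", code = "J038",
                             day = 5L, stringsAsFactors = FALSE)
  res <- apply_eligibility(bind_patients(p))
  expect_equal(nrow(res$cohort$hospitalizations), 1L)

  # same procedure with an ESRD comorbidity at admission: maintenance
  p$diagnoses <- data.frame(hospitalization_id = "X", icd10 = "N18.5",
                            role = "comorbidity_at_admission",
                            stringsAsFactors = FALSE)
  res <- apply_eligibility(bind_patients(p))
  expect_equal(nrow(res$cohort$hospitalizations), 0L)
})

test_that("attrition conserves counts and eligibility is idempotent", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 11))
  co <- inject_exclusions(co, list(under_18 = 2, late_surgery = 2,
                                   transplant = 1, dialysis_esrd = 1,
                                   high_baseline = 2, missing_baseline = 1,
                                   missing_followup = 1), seed = 12)
  res <- apply_eligibility(co)
  att <- as.data.frame(res$attrition)
  expect_equal(att$n_remaining[1] - sum(att$n_excluded),
               att$n_remaining[nrow(att)])
  expect_equal(nrow(res$cohort$hospitalizations), 150 - 10)
  expect_true(all(diff(att$n_remaining) <= 0))

  # attribution matches the injected reasons
  truth <- co$truth
  marked <- truth$hospitalization_id[!is.na(truth$excl_reason)]
  expect_setequal(unname(res$excluded_ids), marked)

  res2 <- apply_eligibility(apply_eligibility(co)$cohort)
  expect_equal(sum(as.data.frame(res2$attrition)$n_excluded), 0L)
})

test_that("grouping the missing-creatinine rows preserves the final cohort", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 3))
  co <- inject_exclusions(co, list(missing_baseline = 2,
                                   missing_followup = 3), seed = 4)
  a <- apply_eligibility(co)
  b <- apply_eligibility(co, group_missing = TRUE)
  expect_equal(a$cohort$hospitalizations, b$cohort$hospitalizations)
  bat <- as.data.frame(b$attrition)
  expect_equal(
    bat$n_excluded[bat$criterion == "no_baseline_or_followup_creatinine"], 5L)
})
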