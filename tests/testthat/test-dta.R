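test_that("contingency construction matches enumerated counts", {
  t <- build_contingency(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  t <- build_contingency(c(TRUE, TRUE, FALSE, FALSE),
                         c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 0L, fp = 1L, fn = 2L, tn = 1L))
  expect_error(build_contingency(c(TRUE, FALSE), TRUE), "length")
  expect_error(contingency_2x2(-1, 0, 0, 1), "non-negative")
})

test_that("Clopper-Pearson matches the exact binomial test and closed forms", {
  # closed form at x = 0: upper = 1 - (alpha/2)^(1/n)
  ci <- clopper_pearson(0, 10)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 10))
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)

  for (case in list(c(27, 663), c(1, 30), c(500, 1000), c(6703, 6711))) {
    got <- clopper_pearson(case[1], case[2])
    want <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(unname(got), as.numeric(want))
  }
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(clopper_pearson(1, 2, level = 1), "level")
})

test_that("metric estimates and intervals reproduce the worked 2x2 examples", {
  f <- compute_metrics(contingency_2x2(27, 8, 636, 6703))
  fmt <- setNames(format_metrics(f)$formatted, f$metrics$metric)
  expect_equal(fmt[["sensitivity"]], "4.1% (2.7-5.9%)")
  expect_equal(fmt[["specificity"]], "99.9% (99.8-99.9%)")
  expect_equal(fmt[["ppv"]], "77.1% (59.9-89.6%)")
  expect_equal(fmt[["npv"]], "91.3% (90.7-92.0%)")
  expect_equal(fmt[["lr_plus"]], "34.2 (15.6-74.9)")
  expect_equal(fmt[["lr_minus"]], "0.96 (0.95-0.98)")
  expect_equal(round(coef(f)[["dor"]], 1), 35.6)

  f <- compute_metrics(contingency_2x2(21, 14, 138, 7201))
  est <- coef(f)
  expect_equal(round(100 * est[["sensitivity"]], 1), 13.2)
  expect_equal(round(100 * est[["npv"]], 1), 98.1)
  expect_equal(round(est[["dor"]], 1), 78.3)
})

test_that("degenerate perfect test is flagged, not an error", {
  f <- compute_metrics(contingency_2x2(5, 0, 0, 5))
  est <- coef(f)
  expect_equal(est[["sensitivity"]], 1)
  expect_equal(est[["specificity"]], 1)
  expect_true(is.infinite(est[["lr_plus"]]))
  m <- f$metrics
  expect_equal(m$flag[m$metric == "lr_plus"], "infinite")
  expect_equal(m$flag[m$metric == "lr_minus"], "continuity_corrected")
})

test_that("DOR and prevalence-odds identities hold on random tables", {
  set.seed(7)
  for (rep in 1:50) {
    cells <- 1 + stats::rpois(4, lambda = sample(c(3, 30, 300), 1))
    f <- compute_metrics(do.call(contingency_2x2, as.list(cells)))
    est <- coef(f)
    expect_equal(est[["dor"]], est[["lr_plus"]] / est[["lr_minus"]],
                 tolerance = 1e-9)
    prev <- f$prevalence
    expect_equal(est[["ppv"]] / (1 - est[["ppv"]]),
                 est[["lr_plus"]] * prev / (1 - prev), tolerance = 1e-9)
    ok <- f$metrics[!nzchar(f$metrics$flag), ]
    expect_true(all(ok$lower <= ok$estimate + 1e-12 &
                    ok$estimate <= ok$upper + 1e-12))
  }
})

test_that("index test uses complication-role codes and the code set", {
  d <- data.frame(
    hospitalization_id = c("A", "B", "C", "D"),
    icd10 = c("N17.9", "N17.0", "N99.0", "I10"),
    role = c("complication_in_hospital", "comorbidity_at_admission",
             "complication_in_hospital", "complication_in_hospital"),
    stringsAsFactors = FALSE)
  ids <- c("A", "B", "C", "D", "E")
  narrow <- index_from_codes(d, ids, "n17_only")
  expect_equal(unname(narrow), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  wide <- index_from_codes(d, ids, "expanded")
  expect_equal(unname(wide), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(wide | !narrow))  # expanded is a superset
})

test_that("stage-restricted reference keeps the cohort denominator", {
  adj <- data.frame(hospitalization_id = sprintf("H%d", 1:4),
                    stage = c(0L, 1L, 2L, 3L))
  expect_equal(unname(stage_restricted_reference(adj, 2)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(stage_restricted_reference(adj, 1)),
               adj$stage >= 1)  # min_stage = 1 is the overall reference
  none <- data.frame(hospitalization_id = "H1", stage = 0L)
  expect_false(any(stage_restricted_reference(none, 3)))
})

test_that("subgroup metrics partition the cohort and recover stratum rates", {
  # single-stratum cohort: stratified fit equals the overall fit
  set.seed(21)
  d <- data.frame(reference = runif(400) < 0.2, index = runif(400) < 0.05,
                  egfr_stratum = "ge60", admission_type = "planned",
                  surgery_category = "abdominal", stringsAsFactors = FALSE)
  s <- subgroup_metrics(d, "admission_type")
  expect_equal(coef(s$fits$planned), coef(dta(d$reference, d$index)))
  expect_null(s$fits$emergent)
  expect_equal(sum(s$counts), nrow(d))

  # stratum-specific coding sensitivity {0.01, 0.07, 0.14} is recovered
  set.seed(22)
  per <- c(ge60 = 0.01, `30to59.9` = 0.07, `15to29.9` = 0.14)
  n_per <- 6000L
  d <- do.call(rbind, lapply(names(per), function(st) {
    ref <- runif(n_per) < 0.2
    idx <- logical(n_per)
    idx[ref] <- runif(sum(ref)) < per[[st]]
    data.frame(reference = ref, index = idx, egfr_stratum = st,
               admission_type = "planned", surgery_category = "abdominal",
               stringsAsFactors = FALSE)
  }))
  s <- subgroup_metrics(d, "egfr_stratum")
  expect_equal(sum(s$counts), nrow(d))
  for (st in names(per)) {
    est <- coef(s$fits[[st]])[["sensitivity"]]
    n_ref <- with(s$fits[[st]]$table, tp + fn)
    se <- sqrt(per[[st]] * (1 - per[[st]]) / n_ref)
    expect_lt(abs(est - per[[st]]), 3 * se)
  }
})
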