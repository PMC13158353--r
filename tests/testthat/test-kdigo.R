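meas <- function(day, value, setting = "inpatient",
                 id = "H1") {
  data.frame(hospitalization_id = rep(id, length(day)), day = day,
             value = value, setting = rep(setting, length.out = length(day)),
             stringsAsFactors = FALSE)
}

test_that("baseline estimation honours method and the 7-365 day window", {
  m <- meas(c(-30, -10), c(0.9, 1.1), "outpatient")
  b <- compute_baseline(m, surgery_day = 0, method = "mean_outpatient_7_365")
  expect_equal(b$value, 1.0)
  expect_equal(b$n_contributing, 2L)

  b <- compute_baseline(m, 0, "latest_outpatient_7_365")
  expect_equal(b$value, 1.1)
  expect_equal(b$n_contributing, 1L)

  # enumeration over candidate lags: only lags in [7, 365] qualify
  for (lag in c(5, 6, 366, 400)) {
    b <- compute_baseline(meas(-lag, 1.0, "outpatient"), 0,
                          "mean_outpatient_7_365")
    expect_false(b$available)
    expect_true(is.na(b$value))
  }
  for (lag in c(7, 8, 200, 365)) {
    b <- compute_baseline(meas(-lag, 1.0, "outpatient"), 0,
                          "mean_outpatient_7_365")
    expect_true(b$available)
  }

  # inpatient variant: most recent strictly before surgery
  m2 <- rbind(meas(c(0, 1), c(0.8, 0.9)), meas(2, 1.4))
  b <- compute_baseline(m2, 2, "latest_inpatient_presurgery")
  expect_equal(b$value, 0.9)
  b <- compute_baseline(meas(-3, 1.0, "outpatient"), 2,
                        "latest_inpatient_presurgery")
  expect_false(b$available)
})

test_that("baseline estimate carries eGFR and stratum when demographics given", {
  b <- compute_baseline(meas(-30, 0.8, "outpatient"), 0,
                        "mean_outpatient_7_365", age = 62, sex = "male")
  expect_equal(round(b$egfr, 1), 75.8)
  expect_equal(b$egfr_stratum, "ge60")
})

test_that("daily_max keeps the highest same-day value and sorts output", {
  m <- meas(c(1, 1, 1, 3, 2), c(1.2, 1.5, 1.3, 0.9, 2.0))
  out <- daily_max(m)
  expect_equal(out$day, c(1, 2, 3))
  expect_equal(out$value, c(1.5, 2.0, 0.9))

  one_per_day <- meas(1:4, c(1, 2, 3, 4))
  expect_equal(daily_max(one_per_day)$value, 1:4 * 1.0)
  expect_equal(nrow(daily_max(meas(integer(), numeric()))), 0L)
})

test_that("adjudication reproduces the canonical rule examples", {
  # absolute rise 0.31 mg/dL within 2 days
  a <- adjudicate_aki(data.frame(day = c(0, 2), value = c(1.1, 1.31)),
                      baseline = 1.0, surgery_day = 0)
  expect_true(a$positive)
  expect_equal(a$stage, 1L)
  expect_equal(a$trigger, "absolute_rise")

  # ratio 2.0/0.9 = 2.22 -> stage 2
  a <- adjudicate_aki(data.frame(day = 1, value = 2.0), baseline = 0.9,
                      surgery_day = 0)
  expect_equal(a$stage, 2L)
  expect_equal(a$trigger, "relative_rise")

  # below both thresholds -> firm negative
  a <- adjudicate_aki(data.frame(day = 1, value = 1.2), baseline = 1.0,
                      surgery_day = 0)
  expect_false(a$positive)
  expect_true(a$evaluable)

  # no creatinine rise but dialysis on day 3 -> stage 3 via RRT
  a <- adjudicate_aki(data.frame(day = c(0, 1), value = c(1.0, 1.1)),
                      baseline = 1.0, rrt_days = 3L, surgery_day = 0)
  expect_equal(a$stage, 3L)
  expect_equal(a$trigger, "rrt")
  expect_equal(a$trigger_day, 3L)
})

test_that("absence of in-window data is flagged, not counted as negative", {
  a <- adjudicate_aki(data.frame(day = integer(), value = numeric()),
                      baseline = 1.0, surgery_day = 0)
  expect_false(a$evaluable)
  expect_false(a$positive)
  # RRT alone is still adjudicable
  a <- adjudicate_aki(data.frame(day = integer(), value = numeric()),
                      baseline = 1.0, rrt_days = 2L, surgery_day = 0)
  expect_true(a$evaluable)
  expect_equal(a$stage, 3L)
})

test_that("creatinine >= 4 promotes to stage 3 only under the configured gate", {
  p <- data.frame(day = 1, value = 4.0)  # baseline 3.8: rise 0.2, ratio 1.05
  gated <- adjudicate_aki(p, baseline = 3.8, surgery_day = 0,
                          scr4_requires_aki = TRUE)
  expect_false(gated$positive)
  open <- adjudicate_aki(p, baseline = 3.8, surgery_day = 0,
                         scr4_requires_aki = FALSE)
  expect_equal(open$stage, 3L)
  expect_equal(open$trigger, "scr_ge4")
})

test_that("rolling 48h comparator differs from the vs-baseline variant", {
  # dip to 0.8 on day 5 then 1.15 on day 6: a 0.35 rise within the rolling
  # window, but only +0.15 (ratio 1.15) against the baseline itself
  p <- data.frame(day = c(5, 6), value = c(0.8, 1.15))
  rolling <- adjudicate_aki(p, baseline = 1.0, surgery_day = 0)
  expect_equal(rolling$stage, 1L)
  vsbl <- adjudicate_aki(p, baseline = 1.0, surgery_day = 0,
                         absolute_rule = "vs_baseline")
  expect_false(vsbl$positive)
})

test_that("same-day absolute and relative triggers resolve to relative", {
  a <- adjudicate_aki(data.frame(day = 0, value = 1.6), baseline = 1.0,
                      surgery_day = 0)
  expect_equal(a$stage, 1L)
  expect_equal(a$trigger, "relative_rise")
})

test_that("adjudication equals the brute-force oracle on random fixtures", {
  set.seed(101)
  for (rep in 1:300) {
    fx <- random_fixture()
    for (w in c("through_discharge", "days_0_to_7")) {
      for (gate in c(TRUE, FALSE)) {
        got <- adjudicate_aki(fx$postop, fx$baseline, fx$rrt_days,
                              fx$surgery_day, window = w,
                              scr4_requires_aki = gate)
        want <- oracle_adjudicate(fx$postop, fx$baseline, fx$rrt_days,
                                  fx$surgery_day, window = w,
                                  scr4_requires_aki = gate)
        expect_equal(got$positive, want$positive)
        expect_equal(got$stage, want$stage)
        expect_equal(got$evaluable, want$evaluable)
      }
    }
  }
})

test_that("raising any post-operative value never lowers the adjudication", {
  set.seed(202)
  for (rep in 1:150) {
    fx <- random_fixture()
    if (nrow(fx$postop) == 0) next
    base <- adjudicate_aki(fx$postop, fx$baseline, fx$rrt_days,
                           fx$surgery_day)
    j <- sample(nrow(fx$postop), 1)
    bumped <- fx$postop
    bumped$value[j] <- bumped$value[j] + runif(1, 0.05, 2)
    after <- adjudicate_aki(bumped, fx$baseline, fx$rrt_days, fx$surgery_day)
    expect_gte(after$stage, base$stage)
    if (base$positive) expect_true(after$positive)
  }
})

test_that("positivity in the 7-day window implies positivity through discharge", {
  set.seed(303)
  for (rep in 1:150) {
    fx <- random_fixture()
    short <- adjudicate_aki(fx$postop, fx$baseline, fx$rrt_days,
                            fx$surgery_day, window = "days_0_to_7")
    long <- adjudicate_aki(fx$postop, fx$baseline, fx$rrt_days,
                           fx$surgery_day, window = "through_discharge")
    if (short$evaluable && short$positive) {
      expect_true(long$positive)
      expect_gte(long$stage, short$stage)
    }
  }
})

test_that("exactly one ratio band fires at any peak ratio", {
  ratios <- c(seq(1.5, 4.5, by = 0.07), 1.5, 2, 3)
  for (r in ratios) {
    bands <- c(r >= 1.5 & r < 2, r >= 2 & r < 3, r >= 3)
    expect_equal(sum(bands), 1L)
    a <- adjudicate_aki(data.frame(day = 1, value = r), baseline = 1,
                        surgery_day = 0)
    expect_equal(a$stage, which(bands))
  }
})
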