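# Seeded synthetic DPC/SS-MIX-style cohort generator with known ground
# truth. Trajectories are constructed so that, against the mean-outpatient
# baseline, every true-AKI case satisfies exactly its assigned stage's
# creatinine rule and every non-AKI case violates all rules, each with a
# guaranteed margin (noise_margin), so the phenotyper must recover the truth
# exactly.

NONCV_CATEGORIES <- c("skin", "musculoskeletal", "nervous_system",
                      "ophthalmic", "otolaryngology", "face_mouth_neck",
                      "thoracic", "abdominal", "urinary_tract", "genital")
NONCV_WEIGHTS <- c(132, 1360, 248, 32, 186, 238, 1009, 1736, 663, 1060)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a surgical validation cohort: ~9% overall AKI incidence
#' with a 76/12/12 percent stage mix, eGFR strata 73.7/24.5/1.9 percent,
#' 1.5% emergent admissions, 9.6% cardiovascular surgery, stage-dependent
#' coding sensitivity averaging ~4% and coding specificity 99.88%.
#'
#' @param n_patients Number of hospitalizations (one patient each).
#' @param seed Integer seed; the entire cohort is a deterministic function
#'   of the configuration including the seed.
#' @param prop_male Fraction of male patients.
#' @param age_range Integer `c(min, max)`, min >= 18.
#' @param age_mean,age_sd Mean/SD of the (truncated normal) age
#'   distribution.
#' @param egfr_stratum_probs Probability vector over baseline eGFR strata
#'   `c(ge60, 30to59.9, 15to29.9)`; must sum to 1.
#' @param prop_emergent Fraction of emergent admissions.
#' @param prop_cardiovascular Fraction of cardiovascular surgeries.
#' @param aki_incidence Named list of true-AKI incidences by surgery x
#'   admission cell: `cv_planned`, `cv_emergent`, `noncv_planned`,
#'   `noncv_emergent`.
#' @param stage_mix Probability vector over stages `c(1, 2, 3)` among AKI
#'   cases; must sum to 1.
#' @param coding_sensitivity_by_stage Named vector: probability that a true
#'   AKI case of each stage receives an N17 complication code.
#' @param coding_specificity Probability that a non-AKI case receives no
#'   N17 complication code; false-positive codes occur at rate
#'   `1 - coding_specificity`.
#' @param prop_stage3_rrt Fraction of stage-3 cases reaching stage 3 through
#'   renal replacement therapy (dialysis procedure code after surgery).
#' @param n_outpatient_baseline_tests Mean number of outpatient baseline
#'   creatinine tests per patient (>= 1; count is `1 + Poisson(mean - 1)`).
#' @param n_postop_tests Mean number of post-operative creatinine tests per
#'   patient (>= 1; same parameterisation).
#' @param noise_margin Fraction in (0, 0.2): guaranteed relative separation
#'   of every trajectory from the KDIGO thresholds.
#' @return Object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_patients = 7374,
                          seed = 1L,
                          prop_male = 3453 / 7374,
                          age_range = c(18L, 95L),
                          age_mean = 61.8, age_sd = 15.9,
                          egfr_stratum_probs = c(ge60 = 5433, `30to59.9` = 1804,
                                                 `15to29.9` = 137) / 7374,
                          prop_emergent = 107 / 7374,
                          prop_cardiovascular = 710 / 7374,
                          aki_incidence = list(cv_planned = 0.238,
                                               cv_emergent = 0.50,
                                               noncv_planned = 0.0705,
                                               noncv_emergent = 0.288),
                          stage_mix = c(`1` = 504, `2` = 82, `3` = 77) / 663,
                          coding_sensitivity_by_stage =
                            c(`1` = 6 / 504, `2` = 6 / 82, `3` = 15 / 77),
                          coding_specificity = 1 - 8 / 6711,
                          prop_stage3_rrt = 48 / 77,
                          n_outpatient_baseline_tests = 3,
                          n_postop_tests = 6.3,
                          noise_margin = 0.1) {
  cfg <- structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         prop_male = prop_male, age_range = as.integer(age_range),
         age_mean = age_mean, age_sd = age_sd,
         egfr_stratum_probs = egfr_stratum_probs,
         prop_emergent = prop_emergent,
         prop_cardiovascular = prop_cardiovascular,
         aki_incidence = aki_incidence, stage_mix = stage_mix,
         coding_sensitivity_by_stage = coding_sensitivity_by_stage,
         coding_specificity = coding_specificity,
         prop_stage3_rrt = prop_stage3_rrt,
         n_outpatient_baseline_tests = n_outpatient_baseline_tests,
         n_postop_tests = n_postop_tests,
         noise_margin = noise_margin),
    class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  fail <- function(msg) stop("invalid cohort configuration: ", msg,
                             call. = FALSE)
  frac <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (length(cfg$n_patients) != 1 || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients)) {
    fail("n_patients must be a non-negative integer")
  }
  if (!frac(cfg$prop_male)) fail("prop_male must be in [0,1]")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] < 18 ||
      cfg$age_range[2] < cfg$age_range[1]) {
    fail("age_range must be [min, max] with min >= 18")
  }
  if (length(cfg$egfr_stratum_probs) != 3 || !frac(cfg$egfr_stratum_probs) ||
      abs(sum(cfg$egfr_stratum_probs) - 1) > 1e-9) {
    fail("egfr_stratum_probs must be 3 probabilities summing to 1")
  }
  if (!frac(cfg$prop_emergent) || !frac(cfg$prop_cardiovascular)) {
    fail("admission/surgery proportions must be in [0,1]")
  }
  need <- c("cv_planned", "cv_emergent", "noncv_planned", "noncv_emergent")
  if (!all(need %in% names(cfg$aki_incidence)) ||
      !frac(unlist(cfg$aki_incidence[need]))) {
    fail(paste("aki_incidence must give fractions for",
               paste(need, collapse = ", ")))
  }
  if (length(cfg$stage_mix) != 3 || !frac(cfg$stage_mix) ||
      abs(sum(cfg$stage_mix) - 1) > 1e-9) {
    fail("stage_mix must be 3 probabilities summing to 1")
  }
  if (length(cfg$coding_sensitivity_by_stage) != 3 ||
      !frac(cfg$coding_sensitivity_by_stage)) {
    fail("coding_sensitivity_by_stage must give 3 fractions")
  }
  if (!frac(cfg$coding_specificity) || !frac(cfg$prop_stage3_rrt)) {
    fail("coding_specificity and prop_stage3_rrt must be in [0,1]")
  }
  if (cfg$n_outpatient_baseline_tests < 1 || cfg$n_postop_tests < 1) {
    fail("test-count means must be >= 1")
  }
  if (!is.finite(cfg$noise_margin) || cfg$noise_margin <= 0 ||
      cfg$noise_margin >= 0.2) {
    fail("noise_margin must be in (0, 0.2)")
  }
  cfg
}

#' Generate a synthetic surgical cohort with known ground truth
#'
#' Produces the four analysis tables (hospitalizations, creatinine
#' measurements, diagnoses, procedures) plus a latent truth table
#' (`true_aki`, `true_stage`, `coded`). All patients pass the eligibility
#' cascade unless exclusions are injected afterwards with
#' [inject_exclusions()]: every patient has outpatient baseline creatinine
#' 7-365 days before surgery, a pre-surgery inpatient creatinine the day
#' before surgery, and post-operative creatinine from the surgery day
#' onwards.
#'
#' @param config A [cohort_config()].
#' @return Object of class `dpc_cohort`: list of data frames
#'   `hospitalizations`, `measurements`, `diagnoses`, `procedures`, `truth`,
#'   plus the `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  n <- cfg$n_patients
  if (n == 0) return(empty_cohort(cfg))
  set.seed(cfg$seed)
  m <- cfg$noise_margin

  ids <- sprintf("H%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$prop_male, "male", "female")
  age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd,
                     cfg$age_range[1], cfg$age_range[2])
  stratum <- sample(names(cfg$egfr_stratum_probs), n, replace = TRUE,
                    prob = cfg$egfr_stratum_probs)
  # floor the sampled eGFR so the implied baseline creatinine stays below
  # the >= 4 mg/dL exclusion (binding only for young low-eGFR patients)
  lo <- pmax(c(ge60 = 60, `30to59.9` = 30, `15to29.9` = 15)[stratum],
             egfr_japanese(rep(3.5, n), age, sex))
  egfr_target <- stats::runif(n,
    min = lo,
    max = c(ge60 = 110, `30to59.9` = 59.9, `15to29.9` = 29.9)[stratum])
  scr0 <- scr_for_egfr(egfr_target, age, sex)

  admission_type <- ifelse(stats::runif(n) < cfg$prop_emergent,
                           "emergent", "planned")
  cv <- stats::runif(n) < cfg$prop_cardiovascular
  surgery_category <- ifelse(cv, "cardiovascular",
                             sample(NONCV_CATEGORIES, n, replace = TRUE,
                                    prob = NONCV_WEIGHTS))
  # surgery 1-3 days after admission so an admission inpatient creatinine
  # exists for the latest-inpatient baseline variant
  surgery_day <- sample(1:3, n, replace = TRUE)

  cell <- paste0(ifelse(cv, "cv", "noncv"), "_", admission_type)
  incidence <- unlist(cfg$aki_incidence)[cell]
  true_aki <- stats::runif(n) < incidence
  true_stage <- integer(n)
  true_stage[true_aki] <- sample(1:3, sum(true_aki), replace = TRUE,
                                 prob = cfg$stage_mix)
  rrt_case <- true_stage == 3 & stats::runif(n) < cfg$prop_stage3_rrt

  n_base <- 1L + stats::rpois(n, max(0, cfg$n_outpatient_baseline_tests - 1))
  n_post <- 1L + stats::rpois(n, max(0, cfg$n_postop_tests - 1))

  meas_id <- meas_day <- meas_val <- meas_set <- vector("list", n)
  proc_id <- proc_code <- proc_day <- vector("list", n)
  diag_id <- diag_icd <- diag_role <- vector("list", n)
  discharge <- integer(n)
  coded <- logical(n)
  alt_flip <- 0L  # alternates absolute/relative stage-1 mechanism

  comorb_pool <- c("I10", "E11.9", "E78.5", "I25.1", "J44.9", "N18.3")
  main_pool <- c("C18.9", "K80.2", "M16.1", "I25.1", "C34.9", "N20.0")
  kpool <- setdiff(sprintf("K%03d", 100:899), "K780")

  # coding status is drawn after the trajectory loop because a relative rise
  # that would cross 4.0 mg/dL escalates the assigned stage (the KDIGO
  # >= 4 mg/dL criterion makes low-eGFR stage-2-by-ratio unattainable)
  for (i in seq_len(n)) {
    s <- surgery_day[i]; b <- scr0[i]
    # outpatient baseline series: mean equals b exactly
    days_b <- sort(sample((s - 365):(s - 7), n_base[i]))
    if (n_base[i] == 1) {
      vals_b <- b
    } else {
      e <- stats::runif(n_base[i], -m / 4, m / 4)
      vals_b <- b * (1 + e - mean(e))
    }
    # pre-surgery inpatient creatinine at the value the baseline estimates
    days_pre <- s - 1L
    vals_pre <- b

    traj <- make_trajectory(true_stage[i], rrt_case[i], b, n_post[i], m,
                            flip = alt_flip)
    if (true_stage[i] == 1) alt_flip <- 1L - alt_flip
    true_stage[i] <- traj$stage
    vals_p <- traj$values
    days_p <- s + seq_len(n_post[i]) - 1L

    # occasional same-day duplicate below the daily value, to exercise the
    # daily-maximum rule
    dup <- stats::runif(1) < 0.2
    if (dup) {
      j <- sample(length(vals_p), 1)
      days_p <- c(days_p, days_p[j])
      vals_p <- c(vals_p, vals_p[j] * stats::runif(1, 0.9, 0.999))
    }

    meas_id[[i]] <- rep(ids[i], length(days_b) + 1L + length(days_p))
    meas_day[[i]] <- c(days_b, days_pre, days_p)
    meas_val[[i]] <- c(vals_b, vals_pre, vals_p)
    meas_set[[i]] <- c(rep("outpatient", length(days_b)),
                       rep("inpatient", 1L + length(days_p)))
    discharge[i] <- s + n_post[i] + 2L

    p_codes <- sample(kpool, 1)
    p_days <- s
    if (rrt_case[i]) {
      p_codes <- c(p_codes, "J038")
      p_days <- c(p_days, s + sample(1:3, 1))
    }
    proc_id[[i]] <- rep(ids[i], length(p_codes))
    proc_code[[i]] <- p_codes
    proc_day[[i]] <- p_days

    coded[i] <- if (true_aki[i]) {
      stats::runif(1) < cfg$coding_sensitivity_by_stage[[true_stage[i]]]
    } else {
      stats::runif(1) >= cfg$coding_specificity
    }

    d_icd <- sample(main_pool, 1)
    d_role <- "main"
    ncom <- sample(0:3, 1)
    if (ncom > 0) {
      d_icd <- c(d_icd, sample(comorb_pool, ncom))
      d_role <- c(d_role, rep("comorbidity_at_admission", ncom))
    }
    if (stats::runif(1) < 0.005) {  # AKI code in the wrong (admission) role
      d_icd <- c(d_icd, "N17.9")
      d_role <- c(d_role, "comorbidity_at_admission")
    }
    if (coded[i]) {
      d_icd <- c(d_icd, sample(c("N17.0", "N17.8", "N17.9"), 1))
      d_role <- c(d_role, "complication_in_hospital")
    }
    diag_id[[i]] <- rep(ids[i], length(d_icd))
    diag_icd[[i]] <- d_icd
    diag_role[[i]] <- d_role
  }

  hosp <- data.frame(
    hospitalization_id = ids, age = age, sex = sex,
    admission_day = 0L, discharge_day = discharge,
    surgery_days = as.character(surgery_day),
    admission_type = admission_type, surgery_category = surgery_category,
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    hospitalization_id = unlist(meas_id), day = as.integer(unlist(meas_day)),
    value = unlist(meas_val), setting = unlist(meas_set),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    hospitalization_id = unlist(diag_id), icd10 = unlist(diag_icd),
    role = unlist(diag_role), stringsAsFactors = FALSE)
  procedures <- data.frame(
    hospitalization_id = unlist(proc_id), code = unlist(proc_code),
    day = as.integer(unlist(proc_day)), stringsAsFactors = FALSE)
  truth <- data.frame(
    hospitalization_id = ids, true_aki = true_aki,
    true_stage = true_stage, coded = coded,
    excl_reason = NA_character_, stringsAsFactors = FALSE)

  structure(list(hospitalizations = hosp, measurements = measurements,
                 diagnoses = diagnoses, procedures = procedures,
                 truth = truth, config = cfg),
            class = "dpc_cohort")
}

# One post-operative creatinine trajectory. b = baseline (mg/dL), np values
# on consecutive days from the surgery day. Guarantees, vs baseline b:
#   stage 0: peak ratio <= 1.5(1-m), max rolling 48h rise <= 0.3(1-m),
#     peak < 4(1-m)
#   stage 1 (relative): peak ratio in [1.5(1+m), min(1.9, 4(1-m)/b)]
#   stage 1 (absolute): rise of 0.3(1+m) within 2 days, peak ratio
#     <= 1.5(1-m), peak <= 4(1-m) -- used for alternating eligible cases
#   stage 2: peak ratio in [2(1+m), min(2.9, 4(1-m)/b)]
#   stage 3: peak ratio in [3(1+m), 3.6] (may cross 4 mg/dL: consistent)
#   stage 3 via RRT: stage-0 trajectory, dialysis code added by caller
# A stage-1/2 assignment whose ratio band cannot stay below 4 mg/dL is
# escalated (stage 1 -> absolute mechanism; stage 2 -> stage 3), because
# under the KDIGO rules such a rise IS higher-stage AKI for that baseline.
make_trajectory <- function(stage, rrt, b, np, m, flip = 0L) {
  flat <- function() {
    a <- min(0.5 - 1.5 * m, 0.15 * (1 - m) / b, 4 * (1 - m) / b - 1)
    a <- max(a, 1e-4)
    b * (1 + stats::runif(np, -a, a))
  }
  if (stage == 0 || rrt) {
    return(list(values = flat(), stage = stage, mechanism = "none"))
  }
  scr4_guard <- 4 * (1 - m) / b  # max peak ratio that avoids the >=4 rule

  if (stage == 1) {
    abs_ok <- b >= 0.3 * (1 + m) / (0.5 - 1.5 * m) &&
      b + 0.3 * (1 + m) <= 4 * (1 - m)
    rel_ok <- 1.5 * (1 + m) <= min(1.9, scr4_guard)
    if (!abs_ok && !rel_ok) {     # any qualifying rise crosses 4 mg/dL
      stage <- 3L
      r <- stats::runif(1, 3 * (1 + m), 3.6)
      return(list(values = peaked(b, b * r, np), stage = stage,
                  mechanism = "relative"))
    }
    if (abs_ok && (flip == 0L || !rel_ok)) {
      cap <- min(1.5 * (1 - m) * b - b, 4 * (1 - m) - b)
      rise <- stats::runif(1, 0.3 * (1 + m), min(cap, 0.3 * (1 + m) + 0.1))
      return(list(values = peaked(b, b + rise, np),
                  stage = 1L, mechanism = "absolute"))
    }
    r <- stats::runif(1, 1.5 * (1 + m), min(1.9, scr4_guard))
  } else if (stage == 2) {
    if (2 * (1 + m) > min(2.9, scr4_guard)) {  # doubling crosses 4 mg/dL
      stage <- 3L
      r <- stats::runif(1, 3 * (1 + m), 3.6)
    } else {
      r <- stats::runif(1, 2 * (1 + m), min(2.9, scr4_guard))
    }
  } else {
    r <- stats::runif(1, 3 * (1 + m), 3.6)
  }
  list(values = peaked(b, b * r, np), stage = as.integer(stage),
       mechanism = "relative")
}

# values start at b, peak (exactly `peak`) on day index min(np, 3), then
# decay back toward b; all values within [b, peak]
peaked <- function(b, peak, np) {
  ip <- min(np, 3L)
  v <- numeric(np)
  for (j in seq_len(np)) {
    if (j < ip) {
      v[j] <- b + (peak - b) * (j - 1) / (ip - 1 + 1e-12) * 0.6
    } else if (j == ip) {
      v[j] <- peak
    } else {
      v[j] <- b + (peak - b) * exp(-(j - ip) / 2)
    }
  }
  v
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  round(out)
}

empty_cohort <- function(cfg) {
  structure(list(
    hospitalizations = data.frame(
      hospitalization_id = character(), age = numeric(), sex = character(),
      admission_day = integer(), discharge_day = integer(),
      surgery_days = character(), admission_type = character(),
      surgery_category = character(), stringsAsFactors = FALSE),
    measurements = data.frame(
      hospitalization_id = character(), day = integer(), value = numeric(),
      setting = character(), stringsAsFactors = FALSE),
    diagnoses = data.frame(
      hospitalization_id = character(), icd10 = character(),
      role = character(), stringsAsFactors = FALSE),
    procedures = data.frame(
      hospitalization_id = character(), code = character(), day = integer(),
      stringsAsFactors = FALSE),
    truth = data.frame(
      hospitalization_id = character(), true_aki = logical(),
      true_stage = integer(), coded = logical(),
      excl_reason = character(), stringsAsFactors = FALSE),
    config = cfg), class = "dpc_cohort")
}

#' @export
print.dpc_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic DPC-style cohort: %d hospitalizations, %d measurements,\n  %d diagnoses, %d procedures",
    nrow(x$hospitalizations), nrow(x$measurements), nrow(x$diagnoses),
    nrow(x$procedures)))
  if (!is.null(x$truth) && nrow(x$truth) > 0) {
    cat(sprintf("; true AKI %d (%.1f%%)", sum(x$truth$true_aki),
                100 * mean(x$truth$true_aki)))
  }
  cat("\n")
  invisible(x)
}

EXCLUSION_REASONS <- c("under_18", "late_surgery", "transplant",
                       "dialysis_esrd", "high_baseline",
                       "missing_baseline", "missing_followup")

#' Inject eligibility exclusions into a synthetic cohort
#'
#' Modifies randomly chosen (previously untouched) patients so that each
#' triggers one named exclusion criterion, and records the intended reason
#' in the truth table. Valid reasons: `under_18`, `late_surgery` (surgery
#' more than 7 days after admission), `transplant`, `dialysis_esrd`
#' (maintenance dialysis / dialysis before surgery), `high_baseline`
#' (baseline creatinine >= 4 mg/dL), `missing_baseline`,
#' `missing_followup`.
#'
#' @param cohort A `dpc_cohort` from [generate_cohort()].
#' @param counts Named list/vector: how many patients to convert per reason.
#' @param seed Integer seed for the selection and modification draws.
#' @return The modified `dpc_cohort`.
#' @export
inject_exclusions <- function(cohort, counts, seed = 1L) {
  counts <- unlist(counts)
  if (length(counts) == 0) return(cohort)
  bad <- setdiff(names(counts), EXCLUSION_REASONS)
  if (length(bad) > 0) {
    stop("unknown exclusion reason(s): ", paste(bad, collapse = ", "),
         "; valid reasons are: ", paste(EXCLUSION_REASONS, collapse = ", "),
         call. = FALSE)
  }
  if (sum(counts) > nrow(cohort$hospitalizations)) {
    stop("requested more exclusions than patients", call. = FALSE)
  }
  set.seed(seed)
  pool <- cohort$hospitalizations$hospitalization_id[
    is.na(cohort$truth$excl_reason)]
  if (sum(counts) > length(pool)) {
    stop("requested more exclusions than untouched patients", call. = FALSE)
  }
  chosen <- sample(pool, sum(counts))
  reason <- rep(names(counts), counts)

  hosp <- cohort$hospitalizations
  meas <- cohort$measurements
  diag <- cohort$diagnoses
  proc <- cohort$procedures
  truth <- cohort$truth

  for (k in seq_along(chosen)) {
    id <- chosen[k]
    hi <- which(hosp$hospitalization_id == id)
    s <- select_index_surgery(hosp[hi, ])
    mi <- meas$hospitalization_id == id
    switch(reason[k],
      under_18 = {
        hosp$age[hi] <- sample(1:17, 1)
      },
      late_surgery = {
        delta <- 8L + sample(0:4, 1) - s
        hosp$surgery_days[hi] <- as.character(s + delta)
        hosp$discharge_day[hi] <- hosp$discharge_day[hi] + delta
        meas$day[mi] <- meas$day[mi] + delta
        pi <- proc$hospitalization_id == id
        proc$day[pi] <- proc$day[pi] + delta
      },
      transplant = {
        diag <- rbind(diag, data.frame(
          hospitalization_id = id, icd10 = "Z94.0",
          role = "comorbidity_at_admission", stringsAsFactors = FALSE))
        proc <- rbind(proc, data.frame(
          hospitalization_id = id, code = "K780", day = s - 30L,
          stringsAsFactors = FALSE))
      },
      dialysis_esrd = {
        diag <- rbind(diag, data.frame(
          hospitalization_id = id, icd10 = "N18.5",
          role = "comorbidity_at_admission", stringsAsFactors = FALSE))
        proc <- rbind(proc, data.frame(
          hospitalization_id = id, code = "J038", day = s - 1L,
          stringsAsFactors = FALSE))
      },
      high_baseline = {
        sel <- mi & meas$setting == "outpatient"
        meas$value[sel] <- stats::runif(sum(sel), 4.2, 5.0)
      },
      missing_baseline = {
        drop <- mi & meas$setting == "outpatient" &
          (s - meas$day) >= 7 & (s - meas$day) <= 365
        meas <- meas[!drop, , drop = FALSE]
      },
      missing_followup = {
        drop <- mi & meas$day >= s & meas$day <= s + 2
        meas <- meas[!drop, , drop = FALSE]
      })
    truth$excl_reason[truth$hospitalization_id == id] <- reason[k]
  }
  rownames(meas) <- rownames(diag) <- rownames(proc) <- NULL
  out <- cohort
  out$hospitalizations <- hosp; out$measurements <- meas
  out$diagnoses <- diag; out$procedures <- proc; out$truth <- truth
  out
}
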