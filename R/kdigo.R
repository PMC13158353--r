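# KDIGO creatinine-based AKI phenotyping.
#
# Measurements are plain data frames with columns
#   hospitalization_id, day (integer offset from admission), value (mg/dL),
#   setting ("outpatient" / "inpatient").
# Days are calendar days; day 0 is admission.

BASELINE_METHODS <- c("mean_outpatient_7_365",
                      "latest_outpatient_7_365",
                      "latest_inpatient_presurgery")

#' Estimate baseline serum creatinine before surgery
#'
#' The primary definition is the arithmetic mean of outpatient creatinine
#' values measured 7-365 days before the index surgery. Two alternative
#' definitions used in sensitivity analyses are the most recent outpatient
#' value in that window and the most recent inpatient value before surgery.
#'
#' @param measurements Data frame of creatinine measurements for one
#'   hospitalization (columns `day`, `value`, `setting`).
#' @param surgery_day Integer day of the index surgery.
#' @param method One of `"mean_outpatient_7_365"`, `"latest_outpatient_7_365"`,
#'   `"latest_inpatient_presurgery"`.
#' @param age,sex Optional; when supplied the baseline eGFR and eGFR stratum
#'   are computed with [egfr_japanese()].
#' @return An object of class `baseline_estimate`: a list with `value`
#'   (mg/dL, `NA` when no qualifying measurement exists), `available`,
#'   `method`, `n_contributing`, and (when age/sex given) `egfr` and
#'   `egfr_stratum`. An unavailable baseline is a signal that the patient
#'   fails inclusion, never an error.
#' @export
compute_baseline <- function(measurements, surgery_day,
                             method = BASELINE_METHODS,
                             age = NULL, sex = NULL) {
  method <- match.arg(method, BASELINE_METHODS)
  stopifnot(is.numeric(surgery_day), length(surgery_day) == 1)
  m <- measurements
  if (method %in% c("mean_outpatient_7_365", "latest_outpatient_7_365")) {
    lag <- surgery_day - m$day
    m <- m[m$setting == "outpatient" & lag >= 7 & lag <= 365, , drop = FALSE]
  } else {
    m <- m[m$setting == "inpatient" & m$day < surgery_day, , drop = FALSE]
  }
  if (nrow(m) == 0) {
    value <- NA_real_; n <- 0L
  } else if (method == "mean_outpatient_7_365") {
    value <- mean(m$value); n <- nrow(m)
  } else {
    value <- m$value[which.max(m$day)]; n <- 1L
  }
  out <- list(value = value, available = n > 0L, method = method,
              n_contributing = n, egfr = NA_real_,
              egfr_stratum = NA_character_)
  if (n > 0L && !is.null(age) && !is.null(sex) && age >= 18) {
    out$egfr <- egfr_japanese(value, age, sex)
    out$egfr_stratum <- as.character(egfr_stratum(out$egfr))
  }
  structure(out, class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  if (!x$available) {
    cat("Baseline creatinine: unavailable (", x$method, ")\n", sep = "")
  } else {
    cat(sprintf("Baseline creatinine: %.3f mg/dL (%s, n = %d)\n",
                x$value, x$method, x$n_contributing))
    if (!is.na(x$egfr)) {
      cat(sprintf("Baseline eGFR: %.1f mL/min/1.73m2 [%s]\n",
                  x$egfr, x$egfr_stratum))
    }
  }
  invisible(x)
}

#' Reduce creatinine measurements to one value per day
#'
#' When several results are recorded for the same hospitalization, day and
#' care setting, the highest value is retained. Output is sorted by
#' hospitalization, day and setting.
#'
#' @param measurements Data frame with columns `hospitalization_id`, `day`,
#'   `value`, `setting`.
#' @return The reduced data frame (same columns).
#' @export
daily_max <- function(measurements) {
  m <- measurements
  if (nrow(m) == 0) return(m)
  o <- order(m$hospitalization_id, m$day, m$setting, -m$value)
  m <- m[o, , drop = FALSE]
  keep <- !duplicated(m[c("hospitalization_id", "day", "setting")])
  m <- m[keep, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Adjudicate AKI presence and stage from post-operative creatinine
#'
#' Applies the creatinine-based KDIGO rules over a detection window starting
#' at the index surgery:
#' \itemize{
#'   \item relative rise: any value >= 1.5 x baseline; stage by peak ratio
#'     band (1: 1.5-1.9, 2: 2.0-2.9, 3: >= 3.0);
#'   \item absolute rise: any value exceeding by >= 0.3 mg/dL the minimum
#'     creatinine observed within the preceding 2 calendar days (rolling
#'     48-hour comparator; see `absolute_rule`) -- stage 1 unless the ratio
#'     band says higher;
#'   \item renal replacement therapy (RRT) initiation in the window: stage 3;
#'   \item serum creatinine >= 4.0 mg/dL: stage 3, by default only when a
#'     rise rule or RRT also fires (`scr4_requires_aki = TRUE`).
#' }
#'
#' The rolling comparator pool for a value on day d holds all post-operative
#' values on days `[d-2, d)`, any pre-surgery inpatient values in that range
#' (argument `presurgery`), and -- when there is no pre-surgery inpatient
#' value -- the baseline estimate treated as if observed on the surgery day.
#' Setting `absolute_rule = "vs_baseline"` compares every in-window value
#' against the baseline alone.
#'
#' @param postop Data frame (`day`, `value`) of post-operative creatinine,
#'   already reduced with [daily_max()]; all days >= `surgery_day`.
#' @param baseline A `baseline_estimate` (or a single numeric value).
#' @param rrt_days Integer days of dialysis initiation (>= surgery day).
#' @param surgery_day Integer day of the index surgery.
#' @param window `"through_discharge"` (all supplied values) or
#'   `"days_0_to_7"` (values and RRT within 7 days after surgery, inclusive).
#' @param scr4_requires_aki Logical; gate the >= 4.0 mg/dL stage-3 promotion
#'   on another rule firing (default `TRUE`).
#' @param absolute_rule `"rolling48h"` (default) or `"vs_baseline"`.
#' @param presurgery Optional data frame (`day`, `value`) of pre-surgery
#'   inpatient creatinine used in the rolling comparator.
#' @return An object of class `aki_adjudication`: list with `evaluable`,
#'   `positive`, `stage` (0 = none, 1-3), `trigger` (`"absolute_rise"`,
#'   `"relative_rise"`, `"scr_ge4"`, `"rrt"`, `"none"`), `trigger_day`,
#'   `peak_ratio`, `peak_value`. `evaluable = FALSE` flags
#'   negative-by-absence: no in-window creatinine and no RRT, so eligibility
#'   should drop the case rather than count a firm negative.
#' @export
adjudicate_aki <- function(postop, baseline, rrt_days = integer(),
                           surgery_day,
                           window = c("through_discharge", "days_0_to_7"),
                           scr4_requires_aki = TRUE,
                           absolute_rule = c("rolling48h", "vs_baseline"),
                           presurgery = NULL) {
  window <- match.arg(window)
  absolute_rule <- match.arg(absolute_rule)
  bl <- if (inherits(baseline, "baseline_estimate")) baseline$value else baseline
  stopifnot(is.numeric(bl), length(bl) == 1, is.finite(bl), bl > 0)
  eps <- 1e-9

  limit <- if (window == "days_0_to_7") surgery_day + 7L else Inf
  p <- postop[postop$day <= limit, , drop = FALSE]
  if (nrow(p) > 0 && any(p$day < surgery_day)) {
    stop("post-operative measurements must not precede the surgery day",
         call. = FALSE)
  }
  rrt <- sort(rrt_days[rrt_days >= surgery_day & rrt_days <= limit])

  if (nrow(p) == 0 && length(rrt) == 0) {
    return(new_adjudication(evaluable = FALSE))
  }

  p <- p[order(p$day), , drop = FALSE]
  have_presurg <- !is.null(presurgery) && nrow(presurgery) > 0

  ratio <- p$value / bl
  rel_fire <- ratio >= 1.5 - eps

  abs_fire <- logical(nrow(p))
  if (nrow(p) > 0) {
    for (i in seq_len(nrow(p))) {
      d <- p$day[i]
      if (absolute_rule == "vs_baseline") {
        comp <- bl
      } else {
        comp <- p$value[p$day >= d - 2 & p$day < d]
        if (have_presurg) {
          comp <- c(comp,
                    presurgery$value[presurgery$day >= d - 2 &
                                     presurgery$day < d])
        } else if (d - surgery_day <= 2) {
          comp <- c(comp, bl)  # baseline anchored at the surgery day
        }
      }
      abs_fire[i] <- length(comp) > 0 && p$value[i] - min(comp) >= 0.3 - eps
    }
  }

  scr4 <- p$value >= 4.0 - eps
  peak_ratio <- if (nrow(p) > 0) max(ratio) else NA_real_
  peak_value <- if (nrow(p) > 0) max(p$value) else NA_real_

  rise_fired <- any(rel_fire) || any(abs_fire) || length(rrt) > 0
  scr4_active <- any(scr4) && (!scr4_requires_aki || rise_fired)

  stage <- 0L
  if (any(abs_fire)) stage <- 1L
  if (any(rel_fire)) stage <- max(stage, ratio_band(max(ratio[rel_fire])))
  if (length(rrt) > 0 || scr4_active) stage <- 3L

  if (stage == 0L) return(new_adjudication(peak_ratio = peak_ratio,
                                           peak_value = peak_value))

  # first firing day; per-day severity decides the recorded trigger,
  # ties broken toward the higher stage, then relative over absolute
  cand <- data.frame(day = integer(), stage = integer(),
                     trigger = character(), pref = integer())
  add <- function(day, st, tr, pref) {
    rbind(cand, data.frame(day = day, stage = st, trigger = tr, pref = pref))
  }
  if (any(rel_fire)) {
    cand <- add(p$day[rel_fire], ratio_band(ratio[rel_fire]),
                "relative_rise", 2L)
  }
  if (any(abs_fire)) cand <- add(p$day[abs_fire], 1L, "absolute_rise", 1L)
  if (length(rrt) > 0) cand <- add(rrt[1], 3L, "rrt", 3L)
  if (scr4_active) cand <- add(p$day[scr4], 3L, "scr_ge4", 2L)

  first_day <- min(cand$day)
  today <- cand[cand$day == first_day, , drop = FALSE]
  today <- today[order(-today$stage, -today$pref), , drop = FALSE]

  new_adjudication(evaluable = TRUE, positive = TRUE, stage = stage,
                   trigger = today$trigger[1], trigger_day = first_day,
                   peak_ratio = peak_ratio, peak_value = peak_value)
}

ratio_band <- function(ratio) {
  eps <- 1e-9
  ifelse(ratio >= 3 - eps, 3L, ifelse(ratio >= 2 - eps, 2L, 1L))
}

new_adjudication <- function(evaluable = TRUE, positive = FALSE, stage = 0L,
                             trigger = "none", trigger_day = NA_integer_,
                             peak_ratio = NA_real_, peak_value = NA_real_) {
  structure(list(evaluable = evaluable, positive = positive,
                 stage = as.integer(stage), trigger = trigger,
                 trigger_day = as.integer(trigger_day),
                 peak_ratio = peak_ratio, peak_value = peak_value),
            class = "aki_adjudication")
}

#' @export
print.aki_adjudication <- function(x, ...) {
  if (!x$evaluable) {
    cat("AKI adjudication: not evaluable (no in-window creatinine, no RRT)\n")
  } else if (!x$positive) {
    cat(sprintf("AKI adjudication: negative (peak ratio %.2f)\n",
                x$peak_ratio))
  } else {
    cat(sprintf(
      "AKI adjudication: positive, stage %d (%s on day %d; peak %.2f mg/dL, ratio %.2f)\n",
      x$stage, x$trigger, x$trigger_day, x$peak_value, x$peak_ratio))
  }
  invisible(x)
}

#' Phenotype every hospitalization in a cohort
#'
#' Runs baseline estimation, daily-maximum reduction and KDIGO adjudication
#' for each hospitalization and returns one row per case.
#'
#' @param cohort A `dpc_cohort` (see [generate_cohort()] / [read_cohort()]) or
#'   a list with data frames `hospitalizations`, `measurements`, `procedures`.
#' @param baseline_method Baseline definition, see [compute_baseline()].
#' @param window Detection window, see [adjudicate_aki()].
#' @param scr4_requires_aki,absolute_rule Passed to [adjudicate_aki()].
#' @param dialysis_codes Procedure codes counted as RRT
#'   (default haemodialysis `J038`, peritoneal dialysis `J042`).
#' @return Data frame with one row per hospitalization: adjudication fields
#'   plus baseline value/method, baseline eGFR and eGFR stratum.
#' @export
phenotype_cohort <- function(cohort,
                             baseline_method = "mean_outpatient_7_365",
                             window = "through_discharge",
                             scr4_requires_aki = TRUE,
                             absolute_rule = "rolling48h",
                             dialysis_codes = c("J038", "J042")) {
  hosp <- cohort$hospitalizations
  meas <- daily_max(cohort$measurements)
  proc <- cohort$procedures

  ids <- hosp$hospitalization_id
  meas_by <- split(meas, factor(meas$hospitalization_id, levels = ids))
  dial <- proc[proc$code %in% dialysis_codes, , drop = FALSE]
  dial_by <- split(dial$day, factor(dial$hospitalization_id, levels = ids))

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    h <- hosp[i, ]
    sday <- select_index_surgery(h)
    m <- meas_by[[i]]
    bl <- compute_baseline(m, sday, baseline_method,
                           age = h$age, sex = h$sex)
    postop <- m[m$setting == "inpatient" & m$day >= sday, c("day", "value")]
    presurg <- m[m$setting == "inpatient" & m$day < sday, c("day", "value")]
    rrt <- dial_by[[i]]
    rrt <- rrt[rrt >= sday]

    if (!bl$available) {
      adj <- new_adjudication(evaluable = FALSE)
    } else {
      adj <- adjudicate_aki(postop, bl, rrt_days = rrt, surgery_day = sday,
                            window = window,
                            scr4_requires_aki = scr4_requires_aki,
                            absolute_rule = absolute_rule,
                            presurgery = if (nrow(presurg)) presurg)
    }
    rows[[i]] <- data.frame(
      hospitalization_id = h$hospitalization_id,
      evaluable = adj$evaluable && bl$available,
      positive = adj$positive, stage = adj$stage, trigger = adj$trigger,
      trigger_day = adj$trigger_day, peak_ratio = adj$peak_ratio,
      peak_value = adj$peak_value,
      baseline = bl$value, baseline_method = bl$method,
      n_baseline = bl$n_contributing,
      egfr = bl$egfr, egfr_stratum = bl$egfr_stratum,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
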