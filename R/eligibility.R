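# Surgical-cohort eligibility cascade with attrition reporting.

#' Index surgery of a hospitalization
#'
#' When a hospitalization contains several general-anaesthesia surgeries,
#' analysis focuses on the first one.
#'
#' @param record One hospitalization row (with a `surgery_days` field holding
#'   integer days, or a `";"`-separated string as stored in the CSV dialect).
#' @return Integer day of the first surgery.
#' @export
select_index_surgery <- function(record) {
  days <- parse_surgery_days(record$surgery_days)
  if (length(days) == 0) {
    stop("not a surgical hospitalization (no surgery days)", call. = FALSE)
  }
  min(days)
}

parse_surgery_days <- function(x) {
  if (is.numeric(x)) return(as.integer(x[!is.na(x)]))
  x <- as.character(x)
  if (length(x) != 1 || is.na(x) || !nzchar(x)) return(integer())
  as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Match ICD-10 codes by prefix
#'
#' Dot-insensitive, case-insensitive prefix matching: prefix `"N17"` matches
#' `N17`, `N17.0` and `N170`.
#'
#' @param codes Character vector of ICD-10 codes.
#' @param prefixes Character vector of prefixes (dots optional).
#' @return Logical vector: does each code match any prefix?
#' @export
icd10_match <- function(codes, prefixes) {
  strip <- function(x) toupper(gsub(".", "", x, fixed = TRUE))
  codes <- strip(codes)
  prefixes <- strip(prefixes)
  Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)),
         rep(FALSE, length(codes)))
}

ELIGIBILITY_STEPS <- c(
  age_under_18                 = "aged under 18 years",
  no_baseline_creatinine       = "no outpatient creatinine 7-365 days before surgery",
  no_followup_creatinine       = "no creatinine within 2 days after surgery",
  surgery_after_day_7          = "index surgery more than 7 days after admission",
  renal_transplant             = "renal transplant (Z94.0 / K780 / K780-2)",
  maintenance_dialysis         = "dialysis with ESRD at admission, or dialysis on/before surgery day",
  high_baseline_scr_or_low_egfr = "baseline creatinine >= 4 mg/dL or eGFR < 15")

#' Apply the eligibility cascade to a cohort
#'
#' Retains adult hospitalizations with an index surgery within 7 days of
#' admission, an outpatient baseline creatinine 7-365 days before surgery, a
#' follow-up creatinine within 2 days after surgery, no renal-transplant
#' markers, no maintenance dialysis (dialysis procedure with an ESRD
#' comorbidity at admission, or any dialysis on/before the surgery day), and
#' a baseline creatinine < 4 mg/dL with baseline eGFR >= 15. Each criterion
#' is record-intrinsic, so the final cohort does not depend on the ordering;
#' only the attribution of exclusions does.
#'
#' @param cohort A `dpc_cohort` (or list of the four tables, optionally with
#'   `truth`).
#' @param baseline_method Baseline definition used for the creatinine/eGFR
#'   exclusion (default mean outpatient 7-365 days).
#' @param esrd_codes ICD-10 prefixes counted as end-stage renal disease when
#'   recorded as a comorbidity at admission.
#' @param dialysis_codes,transplant_proc,transplant_icd Procedure / diagnosis
#'   codes for dialysis and renal transplant.
#' @param group_missing Logical; merge the missing-baseline and
#'   missing-follow-up rows into a single attrition row (flowchart style).
#' @return A list of class `eligibility_result`: `cohort` (the eligible
#'   `dpc_cohort`), `attrition` (data frame of class `attrition_report`:
#'   `criterion`, `label`, `n_excluded`, `n_remaining`), `baselines`
#'   (per-hospitalization baseline value, eGFR and stratum), and
#'   `excluded_ids` (named by triggering criterion).
#' @export
apply_eligibility <- function(cohort,
                              baseline_method = "mean_outpatient_7_365",
                              esrd_codes = c("N18.5", "N18.6", "N18.0"),
                              dialysis_codes = c("J038", "J042"),
                              transplant_proc = c("K780", "K780-2"),
                              transplant_icd = "Z94.0",
                              group_missing = FALSE) {
  hosp <- cohort$hospitalizations
  meas <- cohort$measurements
  diag <- cohort$diagnoses
  proc <- cohort$procedures
  n <- nrow(hosp)
  ids <- hosp$hospitalization_id

  surgery <- vapply(seq_len(n), function(i) select_index_surgery(hosp[i, ]),
                    numeric(1))

  meas_by <- split(meas, factor(meas$hospitalization_id, levels = ids))
  bl_rows <- vector("list", n)
  for (i in seq_len(n)) {
    age_ok <- hosp$age[i] >= 18
    bl <- compute_baseline(meas_by[[i]], surgery[i], baseline_method,
                           age = if (age_ok) hosp$age[i],
                           sex = if (age_ok) hosp$sex[i])
    bl_rows[[i]] <- data.frame(
      hospitalization_id = ids[i], surgery_day = surgery[i],
      baseline = bl$value, n_baseline = bl$n_contributing,
      egfr = bl$egfr, egfr_stratum = bl$egfr_stratum,
      stringsAsFactors = FALSE)
  }
  baselines <- do.call(rbind, bl_rows)

  has_followup <- vapply(seq_len(n), function(i) {
    m <- meas_by[[i]]
    any(m$day >= surgery[i] & m$day <= surgery[i] + 2)
  }, logical(1))

  # outpatient baseline availability is a window criterion, independent of
  # the baseline method used downstream
  has_outpt_baseline <- vapply(seq_len(n), function(i) {
    m <- meas_by[[i]]
    lag <- surgery[i] - m$day
    any(m$setting == "outpatient" & lag >= 7 & lag <= 365)
  }, logical(1))

  diag_by <- split(diag, factor(diag$hospitalization_id, levels = ids))
  proc_by <- split(proc, factor(proc$hospitalization_id, levels = ids))

  transplant <- vapply(seq_len(n), function(i) {
    d <- diag_by[[i]]; p <- proc_by[[i]]
    any(icd10_match(d$icd10, transplant_icd)) ||
      any(p$code %in% transplant_proc)
  }, logical(1))

  dialysis <- vapply(seq_len(n), function(i) {
    d <- diag_by[[i]]; p <- proc_by[[i]]
    dial <- p[p$code %in% dialysis_codes, , drop = FALSE]
    esrd <- any(d$role == "comorbidity_at_admission" &
                icd10_match(d$icd10, esrd_codes))
    (nrow(dial) > 0 && esrd) || any(dial$day <= surgery[i])
  }, logical(1))

  high_baseline <- !is.na(baselines$baseline) &
    (baselines$baseline >= 4 |
       (!is.na(baselines$egfr) & baselines$egfr < 15))

  flags <- list(
    age_under_18                  = hosp$age < 18,
    no_baseline_creatinine        = !has_outpt_baseline,
    no_followup_creatinine        = !has_followup,
    surgery_after_day_7           = surgery > hosp$admission_day + 7,
    renal_transplant              = transplant,
    maintenance_dialysis          = dialysis,
    high_baseline_scr_or_low_egfr = high_baseline)

  remaining <- rep(TRUE, n)
  rows <- list()
  excluded_ids <- character(0)
  for (crit in names(flags)) {
    hit <- remaining & flags[[crit]]
    remaining <- remaining & !flags[[crit]]
    rows[[crit]] <- data.frame(
      criterion = crit, label = unname(ELIGIBILITY_STEPS[crit]),
      n_excluded = sum(hit), n_remaining = sum(remaining),
      stringsAsFactors = FALSE)
    if (any(hit)) {
      excluded_ids <- c(excluded_ids,
                        stats::setNames(ids[hit], rep(crit, sum(hit))))
    }
  }
  attrition <- do.call(rbind, unname(rows))
  attrition <- rbind(
    data.frame(criterion = "initial", label = "surgical hospitalizations",
               n_excluded = 0L, n_remaining = n, stringsAsFactors = FALSE),
    attrition)
  if (group_missing) {
    i1 <- which(attrition$criterion == "no_baseline_creatinine")
    i2 <- which(attrition$criterion == "no_followup_creatinine")
    merged <- data.frame(
      criterion = "no_baseline_or_followup_creatinine",
      label = "no qualifying baseline or follow-up creatinine",
      n_excluded = attrition$n_excluded[i1] + attrition$n_excluded[i2],
      n_remaining = attrition$n_remaining[i2], stringsAsFactors = FALSE)
    attrition <- rbind(attrition[seq_len(i1 - 1), ], merged,
                       attrition[-seq_len(i2), ])
  }
  rownames(attrition) <- NULL
  class(attrition) <- c("attrition_report", "data.frame")

  structure(list(cohort = subset_cohort(cohort, ids[remaining]),
                 attrition = attrition,
                 baselines = baselines,
                 excluded_ids = excluded_ids),
            class = "eligibility_result")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Attrition cascade\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    if (df$criterion[i] == "initial") {
      cat(sprintf("  %-45s n = %d\n", df$label[i], df$n_remaining[i]))
    } else {
      cat(sprintf("  - %-43s -%d -> %d\n", df$label[i], df$n_excluded[i],
                  df$n_remaining[i]))
    }
  }
  invisible(x)
}

#' @export
print.eligibility_result <- function(x, ...) {
  print(x$attrition)
  invisible(x)
}

#' Subset a cohort to a set of hospitalization IDs
#'
#' @param cohort A `dpc_cohort`.
#' @param ids Hospitalization identifiers to keep (order preserved as in the
#'   cohort).
#' @return The filtered `dpc_cohort`.
#' @export
subset_cohort <- function(cohort, ids) {
  keep <- function(df) {
    out <- df[df$hospitalization_id %in% ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  out <- cohort
  for (tab in intersect(names(cohort),
                        c("hospitalizations", "measurements", "diagnoses",
                          "procedures", "truth"))) {
    out[[tab]] <- keep(cohort[[tab]])
  }
  out
}
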