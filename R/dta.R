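# Diagnostic test accuracy: 2x2 construction, metrics and confidence
# intervals for validating an administrative code against a laboratory
# reference standard.

#' Build a 2x2 contingency table from aligned case vectors
#'
#' @param reference Logical vector: reference-standard status per case.
#' @param index Logical vector: index-test (coding) status per case, aligned
#'   with `reference`.
#' @return Object of class `contingency_2x2`: list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
build_contingency <- function(reference, index) {
  if (length(reference) != length(index)) {
    stop("reference and index vectors must have equal length", call. = FALSE)
  }
  if (anyNA(reference) || anyNA(index)) {
    stop("reference and index vectors must not contain NA", call. = FALSE)
  }
  reference <- as.logical(reference); index <- as.logical(index)
  contingency_2x2(tp = sum(reference & index),
                  fp = sum(!reference & index),
                  fn = sum(reference & !index),
                  tn = sum(!reference & !index))
}

#' Construct a 2x2 contingency table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true positive, false
#'   positive, false negative, true negative).
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (beta-quantile) bounds for a binomial proportion: the lower bound is
#' 0 when `x = 0` and the upper bound 1 when `x = n`.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n) {
    stop("require 0 <= x <= n with n >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Computes sensitivity, specificity, PPV, NPV, the likelihood ratios LR+
#' and LR-, and the diagnostic odds ratio (DOR) from a 2x2 table.
#' Proportion intervals are Clopper-Pearson exact; LR intervals use the
#' log method with \eqn{SE(\ln LR+) = \sqrt{1/tp - 1/(tp+fn) + 1/fp -
#' 1/(fp+tn)}} (and the analogous form for LR-); the DOR interval uses
#' Woolf's log method. When a zero cell makes a ratio CI incomputable, all
#' four cells receive a 0.5 continuity correction for the interval only and
#' the metric is flagged `continuity_corrected`; infinite or undefined
#' estimates are flagged, never raised as errors.
#'
#' @param t A `contingency_2x2` (see [contingency_2x2()] /
#'   [build_contingency()]).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `dta`: list with `table` (the 2x2), `n`,
#'   `prevalence`, `conf_level` and `metrics`, a data frame with columns
#'   `metric`, `estimate`, `lower`, `upper`, `flag`.
#' @export
compute_metrics <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  tp <- t$tp; fp <- t$fp; fn <- t$fn; tn <- t$tn
  n <- tp + fp + fn + tn
  if (n == 0) stop("contingency table is empty", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  prop <- function(x, d) {
    if (d == 0) {
      list(est = NA_real_, lo = NA_real_, hi = NA_real_, flag = "undefined")
    } else {
      ci <- clopper_pearson(x, d, conf_level)
      list(est = x / d, lo = ci[["lower"]], hi = ci[["upper"]], flag = "")
    }
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, fp + tn)
  ppv  <- prop(tp, tp + fp)
  npv  <- prop(tn, fn + tn)

  # ratio point estimates from the raw cells
  lrp_est <- ratio_est(sens$est, 1 - spec$est)
  lrm_est <- ratio_est(1 - sens$est, spec$est)
  dor_est <- if (fp == 0 || fn == 0) {
    if (tp == 0 || tn == 0) NA_real_ else Inf
  } else (tp * tn) / (fp * fn)

  # log-method intervals; Haldane-Anscombe 0.5 correction when needed
  corrected <- any(c(tp, fp, fn, tn) == 0)
  a <- tp + 0.5 * corrected; b <- fp + 0.5 * corrected
  cc <- fn + 0.5 * corrected; d <- tn + 0.5 * corrected
  log_ci <- function(est, se) exp(log(est) + c(-1, 1) * z * se)
  sens_c <- a / (a + cc); spec_c <- d / (b + d)
  lrp_ci <- log_ci(sens_c / (1 - spec_c),
                   sqrt(1 / a - 1 / (a + cc) + 1 / b - 1 / (b + d)))
  lrm_ci <- log_ci((1 - sens_c) / spec_c,
                   sqrt(1 / cc - 1 / (a + cc) + 1 / d - 1 / (b + d)))
  dor_ci <- log_ci((a * d) / (b * cc),
                   sqrt(1 / a + 1 / b + 1 / cc + 1 / d))

  ratio_row <- function(est, ci) {
    flag <- if (is.na(est)) "undefined"
            else if (!is.finite(est)) "infinite"
            else if (corrected) "continuity_corrected" else ""
    list(est = est, lo = ci[1], hi = ci[2], flag = flag)
  }
  lrp <- ratio_row(lrp_est, lrp_ci)
  lrm <- ratio_row(lrm_est, lrm_ci)
  dor <- ratio_row(dor_est, dor_ci)

  rows <- list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
               lr_plus = lrp, lr_minus = lrm, dor = dor)
  metrics <- data.frame(
    metric = names(rows),
    estimate = vapply(rows, `[[`, numeric(1), "est"),
    lower = vapply(rows, `[[`, numeric(1), "lo"),
    upper = vapply(rows, `[[`, numeric(1), "hi"),
    flag = vapply(rows, `[[`, character(1), "flag"),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(table = t, n = n, prevalence = (tp + fn) / n,
                 conf_level = conf_level, metrics = metrics),
            class = "dta")
}

ratio_est <- function(num, den) {
  if (is.na(num) || is.na(den)) return(NA_real_)
  if (den == 0) {
    if (num == 0) NA_real_ else Inf
  } else num / den
}

#' Fit diagnostic test accuracy from aligned case vectors
#'
#' Convenience wrapper: [build_contingency()] then [compute_metrics()].
#'
#' @inheritParams build_contingency
#' @inheritParams compute_metrics
#' @return Object of class `dta`.
#' @examples
#' set.seed(1)
#' truth <- runif(500) < 0.1
#' coded <- ifelse(truth, runif(500) < 0.3, runif(500) < 0.01)
#' dta(truth, coded)
#' @export
dta <- function(reference, index, conf_level = 0.95) {
  compute_metrics(build_contingency(reference, index), conf_level)
}

#' @export
print.dta <- function(x, digits = 1, ...) {
  t <- x$table
  cat(sprintf(
    "Diagnostic test accuracy (n = %d, prevalence %.1f%%)\n", x$n,
    100 * x$prevalence))
  cat(sprintf("  2x2: tp = %d, fp = %d, fn = %d, tn = %d\n",
              t$tp, t$fp, t$fn, t$tn))
  f <- format_metrics(x)
  cat(sprintf("  %-12s %s\n", paste0(f$metric, ":"), f$formatted), sep = "")
  invisible(x)
}

#' @export
summary.dta <- function(object, ...) {
  structure(list(fit = object), class = "summary.dta")
}

#' @export
print.summary.dta <- function(x, ...) {
  print(x$fit)
  m <- x$fit$metrics
  flagged <- m[nzchar(m$flag), , drop = FALSE]
  if (nrow(flagged) > 0) {
    cat("  flags:",
        paste(sprintf("%s (%s)", flagged$metric, flagged$flag),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.dta <- function(object, ...) {
  stats::setNames(object$metrics$estimate, object$metrics$metric)
}

#' @export
confint.dta <- function(object, parm, level, ...) {
  m <- object$metrics
  if (!missing(parm)) m <- m[m$metric %in% parm, , drop = FALSE]
  out <- as.matrix(m[c("lower", "upper")])
  rownames(out) <- m$metric
  out
}

#' Format a dta fit at report precision
#'
#' Percentages to one decimal, LR+ and DOR to one decimal, LR- to two --
#' matching conventional report precision for coding-validation tables.
#'
#' @param x A `dta` object.
#' @return Data frame with `metric` and `formatted` columns.
#' @export
format_metrics <- function(x) {
  m <- x$metrics
  fmt1 <- function(metric, est, lo, hi) {
    if (is.na(est)) return("not estimable")
    if (metric %in% c("sensitivity", "specificity", "ppv", "npv")) {
      sprintf("%.1f%% (%.1f-%.1f%%)", 100 * est, 100 * lo, 100 * hi)
    } else if (metric == "lr_minus") {
      sprintf("%.2f (%.2f-%.2f)", est, lo, hi)
    } else if (!is.finite(est)) {
      "infinite"
    } else {
      sprintf("%.1f (%.1f-%.1f)", est, lo, hi)
    }
  }
  data.frame(metric = m$metric,
             formatted = mapply(fmt1, m$metric, m$estimate, m$lower, m$upper),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Index-test status from ICD-10 diagnosis entries
#'
#' A case is index-positive when any diagnosis recorded in the
#' complication-during-hospitalization role matches the code set:
#' `n17_only` matches the N17 block by prefix; `expanded` additionally
#' matches N19 (unspecified renal failure) and N99.0 (postprocedural renal
#' failure). Comorbidity-at-admission and main-diagnosis entries never count.
#'
#' @param diagnoses Data frame with columns `hospitalization_id`, `icd10`,
#'   `role`.
#' @param ids Hospitalization identifiers defining the cohort and output
#'   order.
#' @param code_set `"n17_only"` (default) or `"expanded"`.
#' @return Named logical vector over `ids`.
#' @export
index_from_codes <- function(diagnoses, ids,
                             code_set = c("n17_only", "expanded")) {
  code_set <- match.arg(code_set)
  prefixes <- if (code_set == "expanded") c("N17", "N19", "N99.0") else "N17"
  d <- diagnoses[diagnoses$role == "complication_in_hospital" &
                 icd10_match(diagnoses$icd10, prefixes), , drop = FALSE]
  stats::setNames(ids %in% d$hospitalization_id, ids)
}

#' Stage-restricted reference standard
#'
#' Reference positivity restricted to KDIGO stage `min_stage` or higher;
#' lower-stage AKI cases become reference-negative while the cohort
#' denominator is unchanged.
#'
#' @param adjudications Data frame from [phenotype_cohort()] (needs columns
#'   `hospitalization_id`, `stage`).
#' @param min_stage Minimum stage counted as reference-positive (1, 2 or 3).
#' @return Named logical vector aligned with `adjudications`.
#' @export
stage_restricted_reference <- function(adjudications, min_stage = 1) {
  stopifnot(min_stage %in% 1:3)
  stats::setNames(adjudications$stage >= min_stage,
                  adjudications$hospitalization_id)
}

#' Accuracy metrics within cohort strata
#'
#' Computes a per-stratum 2x2 table and metric set. Strata partition the
#' cohort; an empty stratum is emitted with undefined metrics rather than
#' dropped.
#'
#' @param data Data frame with logical columns `reference` and `index` plus
#'   the stratification columns `egfr_stratum`, `admission_type`,
#'   `surgery_category` (as produced by [run_pipeline()]'s analysis table).
#' @param stratifier One of `"egfr_stratum"`, `"admission_type"`,
#'   `"surgery_cv_vs_noncv"`.
#' @param conf_level Confidence level.
#' @return Object of class `dta_strata`: list with `stratifier`, `levels`,
#'   `fits` (named list of `dta` or `NULL` for empty strata) and `counts`.
#' @export
subgroup_metrics <- function(data,
                             stratifier = c("egfr_stratum", "admission_type",
                                            "surgery_cv_vs_noncv"),
                             conf_level = 0.95) {
  stratifier <- match.arg(stratifier)
  strat <- switch(stratifier,
    egfr_stratum = factor(data$egfr_stratum,
                          levels = c("ge60", "30to59.9", "15to29.9", "lt15")),
    admission_type = factor(data$admission_type,
                            levels = c("planned", "emergent")),
    surgery_cv_vs_noncv = factor(
      ifelse(data$surgery_category == "cardiovascular",
             "cardiovascular", "non_cardiovascular"),
      levels = c("cardiovascular", "non_cardiovascular")))
  if (anyNA(strat)) stop("every case must fall in exactly one stratum",
                         call. = FALSE)
  strat <- droplevels_keep_declared(strat)
  fits <- lapply(levels(strat), function(lv) {
    sel <- strat == lv
    if (!any(sel)) return(NULL)
    dta(data$reference[sel], data$index[sel], conf_level)
  })
  names(fits) <- levels(strat)
  structure(list(stratifier = stratifier, levels = levels(strat),
                 fits = fits, counts = as.integer(table(strat))),
            class = "dta_strata")
}

# keep declared levels that could occur, drop only levels absent from the
# declared design (lt15 is upstream-excluded but may appear in edge cases)
droplevels_keep_declared <- function(f) {
  if ("lt15" %in% levels(f) && !any(f == "lt15")) {
    factor(f, levels = setdiff(levels(f), "lt15"))
  } else f
}

#' @export
print.dta_strata <- function(x, ...) {
  cat("Diagnostic accuracy by", x$stratifier, "\n")
  for (i in seq_along(x$levels)) {
    lv <- x$levels[i]
    cat(sprintf("-- %s (n = %d)\n", lv, x$counts[i]))
    if (is.null(x$fits[[lv]])) cat("   empty stratum: metrics undefined\n")
    else print(x$fits[[lv]])
  }
  invisible(x)
}
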