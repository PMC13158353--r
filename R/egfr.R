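#' Estimated glomerular filtration rate (Japanese equation)
#'
#' Computes eGFR from serum creatinine, age and sex using the three-variable
#' equation developed for Japanese adults:
#' \deqn{eGFR = 194 \times SCr^{-1.094} \times age^{-0.287}}
#' multiplied by 0.739 for women. Units: mL/min/1.73 m2.
#'
#' @param scr Serum creatinine in mg/dL (positive, finite). Vectorised.
#' @param age Age in years (>= 18). Vectorised.
#' @param sex `"male"` or `"female"`. Vectorised.
#' @return Numeric vector of eGFR values in mL/min/1.73 m2.
#' @examples
#' egfr_japanese(0.80, 62, "male")    # ~75.8
#' egfr_japanese(0.80, 62, "female")  # ~56.0
#' @export
egfr_japanese <- function(scr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be >= 18 years", call. = FALSE)
  }
  out <- 194 * scr^(-1.094) * age^(-0.287)
  out[sex == "female"] <- out[sex == "female"] * 0.739
  out
}

#' Invert the Japanese eGFR equation for serum creatinine
#'
#' Returns the serum creatinine (mg/dL) that yields a target eGFR at the given
#' age and sex. Used by the synthetic generator so that sampled eGFR strata
#' stay consistent with generated creatinine values.
#'
#' @inheritParams egfr_japanese
#' @param egfr Target eGFR in mL/min/1.73 m2 (positive).
#' @return Serum creatinine in mg/dL.
#' @export
scr_for_egfr <- function(egfr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("target eGFR must be positive and finite", call. = FALSE)
  }
  k <- ifelse(sex == "female", 0.739, 1)
  (194 * k * age^(-0.287) / egfr)^(1 / 1.094)
}

#' Classify baseline eGFR into analysis strata
#'
#' Strata: `ge60` (>= 60.0), `30to59.9` (30.0-59.9), `15to29.9` (15.0-29.9)
#' and `lt15` (< 15, excluded from the analysis cohort upstream).
#'
#' @param egfr Numeric eGFR values (mL/min/1.73 m2).
#' @return Factor with levels `ge60`, `30to59.9`, `15to29.9`, `lt15`.
#' @export
egfr_stratum <- function(egfr) {
  cut(egfr,
      breaks = c(-Inf, 15, 30, 60, Inf),
      labels = c("lt15", "15to29.9", "30to59.9", "ge60"),
      right = FALSE)
}

match_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) stop("sex must be 'male' or 'female'", call. = FALSE)
  sex
}
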