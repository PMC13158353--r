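# Brute-force KDIGO adjudication oracle for small fixtures.
#
# Enumerates every single value for the relative rule and every ordered pair
# of observations at most 2 days apart for the absolute rule, with the
# baseline treated as an observation on the surgery day when no pre-surgery
# inpatient value is supplied. Deliberately unoptimised and independent of
# the package's rolling-window implementation.
oracle_adjudicate <- function(postop, baseline, rrt_days = integer(),
                              surgery_day, window = "through_discharge",
                              scr4_requires_aki = TRUE) {
  limit <- if (window == "days_0_to_7") surgery_day + 7 else Inf
  p <- postop[postop$day <= limit, , drop = FALSE]
  rrt <- rrt_days[rrt_days >= surgery_day & rrt_days <= limit]
  if (nrow(p) == 0 && length(rrt) == 0) {
    return(list(positive = FALSE, stage = 0L, evaluable = FALSE))
  }

  rel <- any(p$value / baseline >= 1.5)
  peak_band <- 0L
  if (nrow(p) > 0) {
    r <- max(p$value) / baseline
    peak_band <- if (r >= 3) 3L else if (r >= 2) 2L else if (r >= 1.5) 1L else 0L
  }

  obs_day <- c(p$day, surgery_day)      # baseline as a virtual observation
  obs_val <- c(p$value, baseline)
  virt <- c(rep(FALSE, nrow(p)), TRUE)
  abs_rise <- FALSE
  for (i in seq_along(obs_day)) {
    for (j in seq_len(nrow(p))) {
      gap <- p$day[j] - obs_day[i]
      lo <- if (virt[i]) 0 else 1       # real pairs are distinct days
      if (gap >= lo && gap <= 2 && p$value[j] - obs_val[i] >= 0.3) {
        abs_rise <- TRUE
      }
    }
  }

  scr4 <- nrow(p) > 0 && max(p$value) >= 4
  rise <- rel || abs_rise || length(rrt) > 0
  stage <- 0L
  if (abs_rise) stage <- 1L
  if (rel) stage <- max(stage, peak_band)
  if (length(rrt) > 0) stage <- 3L
  if (scr4 && (!scr4_requires_aki || rise)) stage <- 3L
  list(positive = stage > 0L, stage = stage, evaluable = TRUE)
}

# random small fixture for oracle-equivalence checks; continuous draws make
# threshold coincidences probability-zero
random_fixture <- function() {
  surgery_day <- sample(0:3, 1)
  k <- sample(0:8, 1)
  days <- surgery_day + sort(sample(0:12, k))
  # unrounded draws: exact threshold coincidences have probability zero
  postop <- data.frame(day = days, value = runif(k, 0.3, 5))
  list(postop = postop,
       baseline = runif(1, 0.4, 2.5),
       rrt_days = if (runif(1) < 0.15) surgery_day + sample(0:10, 1)
                  else integer(),
       surgery_day = surgery_day)
}
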