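# Deterministic cohort whose full-pipeline 2x2 tables are fixed by
# construction: overall (27, 8, 636, 6703), stages 2&3 (21, 14, 138, 7201),
# cardiovascular (24, 7, 148, 531). Every patient: baseline creatinine 1.0
# (outpatient, day -29), surgery day 1, post-op values on days 1 and 2 with
# a peak ratio of 1.7 / 2.2 / 3.2 by stage (1.1 for non-AKI).
make_table2_cohort <- function() {
  blocks <- rbind(
    # surgery,        stage, n,    n_coded
    data.frame(cv = TRUE,  stage = 1L, n = 120L,  coded = 5L),
    data.frame(cv = TRUE,  stage = 2L, n = 26L,   coded = 5L),
    data.frame(cv = TRUE,  stage = 3L, n = 26L,   coded = 14L),
    data.frame(cv = TRUE,  stage = 0L, n = 538L,  coded = 7L),
    data.frame(cv = FALSE, stage = 1L, n = 384L,  coded = 1L),
    data.frame(cv = FALSE, stage = 2L, n = 56L,   coded = 1L),
    data.frame(cv = FALSE, stage = 3L, n = 51L,   coded = 1L),
    data.frame(cv = FALSE, stage = 0L, n = 6173L, coded = 1L))
  n <- sum(blocks$n)
  stage <- rep(blocks$stage, blocks$n)
  cv <- rep(blocks$cv, blocks$n)
  coded <- unlist(mapply(function(n, k) c(rep(TRUE, k), rep(FALSE, n - k)),
                         blocks$n, blocks$coded, SIMPLIFY = FALSE))
  ids <- sprintf("T%06d", seq_len(n))

  peak <- c(`0` = 1.1, `1` = 1.7, `2` = 2.2, `3` = 3.2)[as.character(stage)]
  hosp <- data.frame(
    hospitalization_id = ids, age = 50, sex = "male",
    admission_day = 0L, discharge_day = 10L, surgery_days = "1",
    admission_type = "planned",
    surgery_category = ifelse(cv, "cardiovascular", "abdominal"),
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    hospitalization_id = rep(ids, each = 3),
    day = rep(c(-29L, 1L, 2L), n),
    value = as.vector(rbind(1, 1, peak)),
    setting = rep(c("outpatient", "inpatient", "inpatient"), n),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    hospitalization_id = ids[coded], icd10 = "N17.9",
    role = "complication_in_hospital", stringsAsFactors = FALSE)
  procedures <- data.frame(
    hospitalization_id = character(), code = character(), day = integer(),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    hospitalization_id = ids, true_aki = stage > 0, true_stage = stage,
    coded = coded, excl_reason = NA_character_, stringsAsFactors = FALSE)
  structure(list(hospitalizations = hosp, measurements = measurements,
                 diagnoses = diagnoses, procedures = procedures,
                 truth = truth),
            class = "dpc_cohort")
}

# one handcrafted eligible patient; override fields to break criteria
make_patient <- function(id = "P1", age = 60, sex = "male", surgery_day = 2,
                         baseline = 1.0, postop = c(1.0, 1.05),
                         discharge_day = 10) {
  hosp <- data.frame(
    hospitalization_id = id, age = age, sex = sex, admission_day = 0L,
    discharge_day = discharge_day,
    surgery_days = as.character(surgery_day),
    admission_type = "planned", surgery_category = "abdominal",
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    hospitalization_id = id,
    day = c(surgery_day - 30L, surgery_day - 1L,
            surgery_day + seq_along(postop) - 1L),
    value = c(baseline, baseline, postop),
    setting = c("outpatient", rep("inpatient", 1L + length(postop))),
    stringsAsFactors = FALSE)
  list(hospitalizations = hosp, measurements = measurements,
       diagnoses = data.frame(hospitalization_id = character(),
                              icd10 = character(), role = character(),
                              stringsAsFactors = FALSE),
       procedures = data.frame(hospitalization_id = character(),
                               code = character(), day = integer(),
                               stringsAsFactors = FALSE))
}

bind_patients <- function(...) {
  ps <- list(...)
  out <- lapply(stats::setNames(nm = names(ps[[1]])), function(tab) {
    do.call(rbind, lapply(ps, `[[`, tab))
  })
  structure(out, class = "dpc_cohort")
}
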