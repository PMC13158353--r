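# Fixed CSV dialect for cohort interchange.
#
# hospitalizations.csv: hospitalization_id, age, sex, admission_day,
#   discharge_day, surgery_days (";"-separated), admission_type,
#   surgery_category
# measurements.csv: hospitalization_id, day, value, setting
# diagnoses.csv:    hospitalization_id, icd10, role
# procedures.csv:   hospitalization_id, code, day
# truth.csv (synthetic cohorts only): hospitalization_id, true_aki,
#   true_stage, coded, excl_reason

COHORT_FILES <- c(hospitalizations = "hospitalizations.csv",
                  measurements = "measurements.csv",
                  diagnoses = "diagnoses.csv",
                  procedures = "procedures.csv",
                  truth = "truth.csv")

#' Write a cohort to a directory of CSV tables
#'
#' Writes the four analysis tables (plus `truth.csv` when present) and, for
#' synthetic cohorts, the generator configuration as `config.yaml`.
#'
#' @param cohort A `dpc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(COHORT_FILES)) {
    if (is.null(cohort[[tab]])) next
    utils::write.csv(cohort[[tab]], file.path(dir, COHORT_FILES[[tab]]),
                     row.names = FALSE)
  }
  if (!is.null(cohort$config)) {
    yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a cohort from a directory of CSV tables
#'
#' @param dir Directory containing the CSV dialect written by
#'   [write_cohort()]; `truth.csv` and `config.yaml` are optional.
#' @return A `dpc_cohort`.
#' @export
read_cohort <- function(dir) {
  path <- function(tab) file.path(dir, COHORT_FILES[[tab]])
  read1 <- function(tab, classes) {
    f <- path(tab)
    if (!file.exists(f)) {
      stop("cohort table not found: ", f, call. = FALSE)
    }
    out <- tryCatch(
      utils::read.csv(f, colClasses = classes, stringsAsFactors = FALSE),
      error = function(e) stop("failed to read ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    out
  }
  cohort <- list(
    hospitalizations = read1("hospitalizations",
      c(hospitalization_id = "character", age = "numeric",
        sex = "character", admission_day = "integer",
        discharge_day = "integer", surgery_days = "character",
        admission_type = "character", surgery_category = "character")),
    measurements = read1("measurements",
      c(hospitalization_id = "character", day = "integer",
        value = "numeric", setting = "character")),
    diagnoses = read1("diagnoses",
      c(hospitalization_id = "character", icd10 = "character",
        role = "character")),
    procedures = read1("procedures",
      c(hospitalization_id = "character", code = "character",
        day = "integer")))
  if (file.exists(path("truth"))) {
    cohort$truth <- read1("truth",
      c(hospitalization_id = "character", true_aki = "logical",
        true_stage = "integer", coded = "logical",
        excl_reason = "character"))
  }
  cfg <- file.path(dir, "config.yaml")
  if (file.exists(cfg)) {
    cohort$config <- yaml::read_yaml(cfg)
  }
  structure(cohort, class = "dpc_cohort")
}
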