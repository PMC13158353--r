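# End-to-end orchestration: simulate/load -> eligibility -> phenotype ->
# validate, with a report table, attrition, manifest and sensitivity
# analysis variants.

#' Configuration for a validation pipeline run
#'
#' Exactly one of `input_dir` (CSV tables in the [write_cohort()] dialect)
#' or `cohort` (a [cohort_config()] or `dpc_cohort`) must be given.
#'
#' @param input_dir Directory of input CSV tables, or `NULL`.
#' @param cohort A `cohort_config` (the cohort is simulated at run time,
#'   reseeded from `seed`) or an already-built `dpc_cohort`, or `NULL`.
#' @param baseline_method Baseline creatinine definition
#'   (see [compute_baseline()]).
#' @param window AKI detection window (see [adjudicate_aki()]).
#' @param code_set Index-test code set (see [index_from_codes()]).
#' @param min_stage Minimum KDIGO stage counted as reference-positive.
#' @param stratifiers Subgroup stratifiers to report.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed governing all randomness of the run.
#' @param scr4_requires_aki,absolute_rule Phenotyper switches
#'   (see [adjudicate_aki()]).
#' @param conf_level Confidence level for all intervals.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, cohort = NULL,
                       baseline_method = "mean_outpatient_7_365",
                       window = "through_discharge",
                       code_set = "n17_only",
                       min_stage = 1,
                       stratifiers = c("egfr_stratum", "admission_type",
                                       "surgery_cv_vs_noncv"),
                       out_dir = NULL, seed = 1L,
                       scr4_requires_aki = TRUE,
                       absolute_rule = "rolling48h",
                       conf_level = 0.95) {
  if (is.null(input_dir) == is.null(cohort)) {
    stop("provide exactly one of input_dir or cohort", call. = FALSE)
  }
  baseline_method <- match.arg(baseline_method, BASELINE_METHODS)
  window <- match.arg(window, c("through_discharge", "days_0_to_7"))
  code_set <- match.arg(code_set, c("n17_only", "expanded"))
  stopifnot(min_stage %in% 1:3)
  stratifiers <- match.arg(stratifiers,
                           c("egfr_stratum", "admission_type",
                             "surgery_cv_vs_noncv"), several.ok = TRUE)
  structure(list(input_dir = input_dir, cohort = cohort,
                 baseline_method = baseline_method, window = window,
                 code_set = code_set, min_stage = as.integer(min_stage),
                 stratifiers = stratifiers, out_dir = out_dir,
                 seed = as.integer(seed),
                 scr4_requires_aki = scr4_requires_aki,
                 absolute_rule = absolute_rule, conf_level = conf_level),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML maps directly onto [run_config()] arguments; a `cohort:` block
#' is interpreted as [cohort_config()] arguments.
#'
#' @param path YAML file path.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) {
    raw$cohort <- do.call(cohort_config, raw$cohort)
  }
  do.call(run_config, raw)
}

#' Run the full validation pipeline
#'
#' Simulates or loads a cohort, applies the eligibility cascade, phenotypes
#' every eligible hospitalization against the KDIGO creatinine criteria,
#' derives the index test from ICD-10 complication codes, and computes the
#' accuracy report (overall, stages 2 and 3 restricted, and per-subgroup).
#' With an output directory it writes `attrition.csv`, `adjudications.csv`,
#' `report.csv`, `report.json` (full precision plus flags) and
#' `manifest.json` (configuration echo, seed, package version, row counts
#' and MD5 content hashes of every output). Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param config A `run_config` (or YAML path accepted by
#'   [read_run_config()]).
#' @return Object of class `aki_validation`: list with `report` (formatted
#'   data frame), `fits` (named list of `dta` / `dta_strata`), `attrition`,
#'   `adjudications`, `analysis` (per-case reference/index/strata table),
#'   `manifest`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  cohort <- resolve_cohort(config)
  elig <- apply_eligibility(cohort, baseline_method = config$baseline_method)
  eligible <- elig$cohort

  adj <- phenotype_cohort(eligible,
                          baseline_method = config$baseline_method,
                          window = config$window,
                          scr4_requires_aki = config$scr4_requires_aki,
                          absolute_rule = config$absolute_rule)
  if (any(!adj$evaluable)) {
    # negative-by-absence after eligibility should not happen; drop loudly
    warning(sum(!adj$evaluable),
            " hospitalization(s) not evaluable after eligibility; dropped")
    keep <- adj$hospitalization_id[adj$evaluable]
    eligible <- subset_cohort(eligible, keep)
    adj <- adj[adj$evaluable, , drop = FALSE]
  }

  ids <- adj$hospitalization_id
  hosp <- eligible$hospitalizations
  analysis <- data.frame(
    hospitalization_id = ids,
    reference = unname(stage_restricted_reference(adj, config$min_stage)),
    stage = adj$stage,
    index = unname(index_from_codes(eligible$diagnoses, ids,
                                    config$code_set)),
    egfr_stratum = adj$egfr_stratum,
    admission_type = hosp$admission_type[match(ids, hosp$hospitalization_id)],
    surgery_category =
      hosp$surgery_category[match(ids, hosp$hospitalization_id)],
    stringsAsFactors = FALSE)

  fits <- list(overall = dta(analysis$reference, analysis$index,
                             config$conf_level),
               stages_2_3 = dta(analysis$stage >= 2, analysis$index,
                                config$conf_level))
  for (s in config$stratifiers) {
    fits[[s]] <- subgroup_metrics(analysis, s, config$conf_level)
  }

  report <- build_report(fits, analysis)
  manifest <- list(
    package = "akivalid",
    version = as.character(utils::packageVersion("akivalid")),
    seed = config$seed,
    settings = config[c("baseline_method", "window", "code_set",
                        "min_stage", "stratifiers", "scr4_requires_aki",
                        "absolute_rule", "conf_level")],
    counts = list(
      input_hospitalizations = nrow(cohort$hospitalizations),
      eligible = nrow(eligible$hospitalizations),
      excluded = nrow(cohort$hospitalizations) -
        nrow(eligible$hospitalizations),
      reference_positive = sum(analysis$reference),
      index_positive = sum(analysis$index)))

  out <- structure(list(report = report, fits = fits,
                        attrition = elig$attrition, adjudications = adj,
                        analysis = analysis, manifest = manifest,
                        config = config),
                   class = "aki_validation")
  if (!is.null(config$out_dir)) {
    out$manifest$outputs <- write_run_outputs(out, config$out_dir)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(out$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  message(sprintf(
    "pipeline: read %d, excluded %d, eligible %d, reference-positive %d, index-positive %d",
    out$manifest$counts$input_hospitalizations,
    out$manifest$counts$excluded, out$manifest$counts$eligible,
    out$manifest$counts$reference_positive,
    out$manifest$counts$index_positive))
  out
}

resolve_cohort <- function(config) {
  if (!is.null(config$input_dir)) return(read_cohort(config$input_dir))
  if (inherits(config$cohort, "dpc_cohort")) return(config$cohort)
  cfg <- config$cohort
  cfg$seed <- config$seed  # one recorded seed governs the whole run
  generate_cohort(cfg)
}

build_report <- function(fits, analysis) {
  n_total <- nrow(analysis)
  row_for <- function(label, fit, sel) {
    if (is.null(fit)) {
      return(data.frame(row = label, n = sum(sel), n_reference = 0L,
                        pct_reference = NA_real_, n_index = 0L,
                        pct_index = NA_real_,
                        sensitivity = "not estimable",
                        specificity = "not estimable",
                        ppv = "not estimable", npv = "not estimable",
                        lr_plus = "not estimable",
                        lr_minus = "not estimable", dor = "not estimable",
                        stringsAsFactors = FALSE))
    }
    t <- fit$table
    f <- format_metrics(fit)
    fmt <- stats::setNames(f$formatted, f$metric)
    data.frame(row = label, n = fit$n,
               n_reference = t$tp + t$fn,
               pct_reference = round(100 * (t$tp + t$fn) / fit$n, 1),
               n_index = t$tp + t$fp,
               pct_index = round(100 * (t$tp + t$fp) / fit$n, 1),
               sensitivity = fmt[["sensitivity"]],
               specificity = fmt[["specificity"]],
               ppv = fmt[["ppv"]], npv = fmt[["npv"]],
               lr_plus = fmt[["lr_plus"]], lr_minus = fmt[["lr_minus"]],
               dor = fmt[["dor"]], stringsAsFactors = FALSE)
  }
  rows <- list(row_for("overall", fits$overall, rep(TRUE, n_total)),
               row_for("stages_2_3", fits$stages_2_3, rep(TRUE, n_total)))
  for (s in setdiff(names(fits), c("overall", "stages_2_3"))) {
    strata <- fits[[s]]
    for (i in seq_along(strata$levels)) {
      lv <- strata$levels[i]
      rows[[length(rows) + 1]] <-
        row_for(paste0(s, ": ", lv), strata$fits[[lv]],
                rep(FALSE, strata$counts[i]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(attrition = file.path(out_dir, "attrition.csv"),
             adjudications = file.path(out_dir, "adjudications.csv"),
             report = file.path(out_dir, "report.csv"),
             report_json = file.path(out_dir, "report.json"))
  utils::write.csv(as.data.frame(run$attrition), paths[["attrition"]],
                   row.names = FALSE)
  utils::write.csv(run$adjudications, paths[["adjudications"]],
                   row.names = FALSE)
  utils::write.csv(run$report, paths[["report"]], row.names = FALSE)
  full <- lapply(run$fits, function(f) {
    if (inherits(f, "dta")) dta_as_list(f)
    else lapply(f$fits, function(g) if (is.null(g)) NULL else dta_as_list(g))
  })
  jsonlite::write_json(full, paths[["report_json"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  lapply(stats::setNames(nm = names(paths)), function(k) {
    list(file = basename(paths[[k]]),
         md5 = unname(tools::md5sum(paths[[k]])))
  })
}

dta_as_list <- function(f) {
  list(n = f$n, prevalence = f$prevalence,
       table = f$table[c("tp", "fp", "fn", "tn")],
       conf_level = f$conf_level,
       metrics = f$metrics)
}

#' @export
print.aki_validation <- function(x, ...) {
  cat("ICD-10 AKI coding validity against the KDIGO reference standard\n")
  cat(sprintf("  cohort n = %d; reference-positive %d; index-positive %d\n",
              x$manifest$counts$eligible,
              x$manifest$counts$reference_positive,
              x$manifest$counts$index_positive))
  print(x$report[c("row", "n_reference", "n_index", "sensitivity",
                   "specificity", "ppv", "npv")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.aki_validation <- function(object, ...) {
  print(object$attrition)
  print(object)
  invisible(object)
}

#' Run the main analysis plus the four sensitivity-analysis variants
#'
#' Variants: `sa1_window7` restricts AKI detection to 7 days after surgery;
#' `sa2_latest_outpatient` uses the most recent outpatient baseline value
#' instead of the mean; `sa3_latest_inpatient` uses the most recent
#' pre-surgery inpatient value; `sa4_expanded_codes` widens the index code
#' set to N17.x, N19 and N99.0.
#'
#' @param config Base `run_config`; each variant changes exactly one
#'   setting. When `out_dir` is set, each run writes to a subdirectory.
#' @return Named list of class `aki_sensitivity_suite` with elements
#'   `main`, `sa1_window7`, `sa2_latest_outpatient`, `sa3_latest_inpatient`,
#'   `sa4_expanded_codes` (each an `aki_validation`).
#' @export
run_sensitivity_suite <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  variants <- list(
    main = identity,
    sa1_window7 = function(c) { c$window <- "days_0_to_7"; c },
    sa2_latest_outpatient = function(c) {
      c$baseline_method <- "latest_outpatient_7_365"; c },
    sa3_latest_inpatient = function(c) {
      c$baseline_method <- "latest_inpatient_presurgery"; c },
    sa4_expanded_codes = function(c) { c$code_set <- "expanded"; c })
  out <- lapply(names(variants), function(nm) {
    cfg <- variants[[nm]](config)
    if (!is.null(config$out_dir)) {
      cfg$out_dir <- file.path(config$out_dir, nm)
    }
    run_pipeline(cfg)
  })
  names(out) <- names(variants)
  structure(out, class = "aki_sensitivity_suite")
}

#' @export
print.aki_sensitivity_suite <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    overall <- x[[nm]]$report[x[[nm]]$report$row == "overall", ]
    cat(sprintf("  n_ref = %d, n_index = %d, sens = %s, spec = %s\n",
                overall$n_reference, overall$n_index, overall$sensitivity,
                overall$specificity))
  }
  invisible(x)
}
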