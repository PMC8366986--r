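#' Run the full balance-alteration study replica
#'
#' Orchestrates the complete analysis on a synthetic study generated from
#' `config` (all stages reproducible from its seed), in the order of the
#' reference analysis plan:
#' descriptive characteristics by group, the 78-index ROC/AUC screen, the
#' Youden cut-off for the top index with its confusion statistics, and the
#' adjusted logistic model (dichotomized top index + sex + age + BMI) with
#' Hosmer-Lemeshow calibration and model AUC. The Cochran planning
#' calculation that sized the reference study is included in the report
#' metadata.
#'
#' @param config A [generator_config()].
#' @param hl_groups Hosmer-Lemeshow groups for the model stage (default 10).
#' @param write_dir Optional directory: if given, the stage tables are
#'   written as CSV and the full report as `study_report.json`.
#' @return A list of class `study_report` with elements `meta` (schema
#'   version, seed, n, group sizes, sample-size planning), `table1`,
#'   `screen`, `best_index`, `cutoff`, `model` and `predictions_example`.
#' @export
run_balance_study <- function(config = generator_config(), hl_groups = 10,
                              write_dir = NULL) {
  cohort <- generate_cohort(config)
  metrics <- compute_study_metrics(cohort, config)

  tab1 <- table_one(cohort,
                    vars = c("age", "sex", "multimorbidity", "polypharmacy",
                             "falls_last_year", "bmi", "gait_speed", "squats"))

  scr <- screen_indexes(metrics[, setdiff(names(metrics), "subject_id")],
                        cohort$balance_alteration)
  best <- scr$index[1]
  scores <- metrics[[best]]
  roc <- roc_curve(scores, cohort$balance_alteration)
  cut <- youden_cutoff(roc)

  model_data <- data.frame(
    mvelap_dic = as.numeric(dichotomize(scores, cut$cutoff)),
    sex_woman = as.numeric(cohort$sex == "woman"),
    age = cohort$age,
    bmi = cohort$bmi,
    balance_alteration = cohort$balance_alteration)
  fit <- fit_logistic(model_data, hl_groups = hl_groups)

  report <- structure(list(
    meta = list(schema_version = "1.0",
                seed = config$seed,
                n_subjects = config$n_subjects,
                n_with = sum(cohort$balance_alteration),
                n_without = sum(!cohort$balance_alteration),
                endpoint_mode = config$endpoint_mode,
                planning = unclass(cochran_sample_size(0.404, 0.05, 0.95))),
    table1 = tab1,
    screen = scr,
    best_index = best,
    index_auc = roc$auc,
    index_auc_ci = suppressWarnings(auc_ci(roc)),
    cutoff = unclass(cut),
    model = list(coefficients = fit$coefficients,
                 hosmer_lemeshow = fit$hosmer_lemeshow[c("chi2", "df", "p_value")],
                 auc = fit$auc, auc_ci = fit$auc_ci,
                 n_used = fit$n_used, n_dropped = fit$n_dropped),
    predictions_example = list(
      low_risk = predict_probability(fit, 0, 0, 70, 22.7),
      high_risk = predict_probability(fit, 1, 1, 80, 33.2))),
    class = "study_report")

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab1, file.path(write_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(scr, file.path(write_dir, "index_screen.csv"), row.names = FALSE)
    utils::write.csv(fit$coefficients, file.path(write_dir, "model_coefficients.csv"),
                     row.names = FALSE)
    write_study_report(report, file.path(write_dir, "study_report.json"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Balance-alteration study report (seed %d, n = %d: %d with / %d without)\n",
              x$meta$seed, x$meta$n_subjects, x$meta$n_with, x$meta$n_without))
  cat(sprintf("  planned sample size (Cochran): %d\n", x$meta$planning$n_required))
  cat(sprintf("  best index: %s, AUC = %.3f (%.3f-%.3f)\n",
              x$best_index, x$index_auc, x$index_auc_ci[1], x$index_auc_ci[2]))
  cat(sprintf("  Youden cut-off: %.2f (sens %.3f, spec %.3f)\n",
              x$cutoff$cutoff, x$cutoff$sensitivity, x$cutoff$specificity))
  cat(sprintf("  adjusted model AUC = %.3f, HL p = %.3f\n",
              x$model$auc, x$model$hosmer_lemeshow$p_value))
  invisible(x)
}

report_fields <- c("meta", "table1", "screen", "best_index", "index_auc",
                   "index_auc_ci", "cutoff", "model", "predictions_example")

#' Write / read / validate a study report
#'
#' The report is serialized as JSON with a versioned schema; both writing
#' and reading validate that every schema field is present.
#'
#' @param report A `study_report` from [run_balance_study()].
#' @param path JSON file path.
#' @return `write_study_report()` returns `path` invisibly;
#'   `read_study_report()` returns the validated report as a list.
#' @export
write_study_report <- function(report, path) {
  validate_study_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_report
#' @export
read_study_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_study_report(report)
  report
}

#' @rdname write_study_report
#' @export
validate_study_report <- function(report) {
  missing_fields <- setdiff(report_fields, names(report))
  if (length(missing_fields)) {
    stop("invalid study report, missing: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.character(report$meta$schema_version), "1.0")) {
    stop("unsupported study report schema version", call. = FALSE)
  }
  invisible(TRUE)
}
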