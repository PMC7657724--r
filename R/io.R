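# Cohort file layout: one directory with patients.csv, responses.csv (grade
# columns `<symptom>.grade`), plans.csv, surveys.csv, etiologies.csv (the
# last two optional). Dates ISO-8601, CSV with header, UTF-8.

#' Write a cohort to a directory of CSV files
#'
#' @param cohort An [epro_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  resp <- cohort$responses
  names(resp)[match(epro_symptoms, names(resp))] <- paste0(epro_symptoms, ".grade")
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(resp, file.path(dir, "responses.csv"), na = "")
  readr::write_csv(cohort$plans, file.path(dir, "plans.csv"), na = "")
  if (!is.null(cohort$surveys)) {
    readr::write_csv(cohort$surveys, file.path(dir, "surveys.csv"), na = "")
  }
  if (!is.null(cohort$etiologies)) {
    readr::write_csv(cohort$etiologies, file.path(dir, "etiologies.csv"), na = "")
  }
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' Reads and validates the tables written by [write_cohort()], enforcing
#' referential integrity (every response and survey row must reference a
#' registry patient) and window containment of response dates.
#'
#' @param dir Directory containing `patients.csv`, `responses.csv`,
#'   `plans.csv` and optionally `surveys.csv`, `etiologies.csv`.
#' @return An [epro_cohort()].
#' @export
read_cohort <- function(dir) {
  read1 <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      rlang::abort(paste0("missing cohort file: ", path), class = "epro_load_error")
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  patients <- read1("patients.csv")
  resp <- read1("responses.csv")
  plans <- read1("plans.csv")
  grade_cols <- paste0(epro_symptoms, ".grade")
  unknown <- setdiff(grep("\\.grade$", names(resp), value = TRUE), grade_cols)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown symptom column in responses.csv: ", unknown[1]),
                 class = "epro_load_error")
  }
  miss <- setdiff(grade_cols, names(resp))
  if (length(miss) > 0) {
    rlang::abort(paste0("responses.csv lacks column(s): ", paste(miss, collapse = ", ")),
                 class = "epro_load_error")
  }
  names(resp)[match(grade_cols, names(resp))] <- epro_symptoms
  resp <- dplyr::mutate(
    resp,
    week_index = as.integer(.data$week_index),
    answer_date = as.Date(.data$answer_date),
    dplyr::across(dplyr::all_of(epro_symptoms), as.integer)
  )
  plans <- dplyr::mutate(plans, start_date = as.Date(.data$start_date),
                         end_date = as.Date(.data$end_date))
  surveys <- if (file.exists(file.path(dir, "surveys.csv"))) read1("surveys.csv")
  etiologies <- if (file.exists(file.path(dir, "etiologies.csv"))) {
    dplyr::mutate(read1("etiologies.csv"),
                  week_index = as.integer(.data$week_index),
                  answer_date = as.Date(.data$answer_date))
  }
  epro_cohort(patients, resp, plans, surveys, etiologies)
}

#' Run the full monitoring-analysis pipeline
#'
#' Executes the stages in order — alert evaluation (with etiology
#' annotations when the cohort carries them), weekly compliance, grade
#' distribution, benefit correlations, per-arm prevalences and survey
#' summary — and writes every table as CSV plus a machine-readable JSON
#' report to `out_dir`. Identical inputs produce byte-identical numeric
#' outputs.
#'
#' @param cohort An [epro_cohort()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param alert_window Week window of the alert analysis (default weeks
#'   1-12).
#' @param config An [alert_config()].
#' @param heatmap Also write the symptom correlation heatmap (PNG).
#' @return List of class `epro_report` with elements `alerts`,
#'   `alert_summary`, `compliance`, `grade_distribution`,
#'   `benefit_correlation`, `correlations`, `prevalence`, `survey` and
#'   `glance`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, alert_window = c(1, 12),
                         config = alert_config(), heatmap = FALSE) {
  if (nrow(cohort$responses) == 0) {
    rlang::abort("cohort has no responses; nothing to analyze",
                 class = "epro_validation_error")
  }
  decisions <- evaluate_alerts(cohort$responses, config)
  if (!is.null(cohort$etiologies)) {
    decisions <- annotate_etiology(decisions, cohort$etiologies)
  }
  summary <- alert_summary(decisions, cohort, window = alert_window)
  compliance <- compute_compliance(cohort$responses, cohort$plans)
  dist <- grade_distribution(cohort)
  corr <- pearson_matrix(symptom_observations(cohort, unit = "questionnaire"))
  ben <- tryCatch(benefit_correlation(cohort), error = function(e) NULL)
  prev <- dplyr::bind_rows(
    itching = prevalence_by_arm(cohort, "itching"),
    chest_pain = prevalence_by_arm(cohort, "chest_pain"),
    .id = "symptom"
  )
  surv <- if (!is.null(cohort$surveys)) survey_summary(cohort$surveys)

  report <- structure(
    list(alerts = decisions, alert_summary = summary, compliance = compliance,
         grade_distribution = dist, benefit_correlation = ben,
         correlations = corr, prevalence = prev, survey = surv,
         glance = glance(cohort)),
    class = "epro_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat_alerts <- dplyr::select(decisions, -"triggers")
    readr::write_csv(flat_alerts, file.path(out_dir, "alerts.csv"), na = "")
    readr::write_csv(compliance, file.path(out_dir, "compliance.csv"), na = "")
    readr::write_csv(dist, file.path(out_dir, "grade_distribution.csv"), na = "")
    if (!is.null(ben)) {
      readr::write_csv(ben, file.path(out_dir, "benefit_correlation.csv"), na = "")
    }
    readr::write_csv(tidy(corr), file.path(out_dir, "symptom_correlations.csv"), na = "")
    readr::write_csv(prev, file.path(out_dir, "prevalence.csv"), na = "")
    if (!is.null(surv)) {
      readr::write_csv(surv, file.path(out_dir, "survey_summary.csv"), na = "")
    }
    jsonlite::write_json(
      list(
        cohort = report$glance,
        alert_rate_pct = summary$rate_pct,
        n_alerts = summary$n_alerts,
        n_questionnaires_in_window = summary$n_questionnaires,
        etiology = summary$etiology,
        by_symptom = summary$by_symptom,
        compliance_range = as.list(compliance_range(compliance))
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    if (isTRUE(heatmap)) {
      try({
        p <- ggplot2::autoplot(corr)
        ggplot2::ggsave(file.path(out_dir, "symptom_heatmap.png"), p,
                        width = 8, height = 7, dpi = 150)
      }, silent = TRUE)
    }
  }
  report
}

#' @export
print.epro_report <- function(x, ...) {
  cat("<epro_report>\n")
  print(x$alert_summary)
  rng <- compliance_range(x$compliance)
  cat("  compliance ", sprintf("%.3f-%.3f", rng[["min"]], rng[["max"]]),
      " questionnaires/patient/week\n", sep = "")
  invisible(x)
}
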