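#' Assemble a cohort object
#'
#' Bundles the registry, longitudinal graded responses, follow-up plans,
#' experience surveys and (optionally) physician etiology annotations into a
#' validated `epro_cohort`.
#'
#' @param patients Registry tibble: `patient_id`, `age`, `sex`, `tumor_type`,
#'   `stage`, `ecog`, `benefit` (one of CR/PR/SD/PD, or `NA` when not
#'   evaluable).
#' @param responses Graded questionnaire tibble: `patient_id`, `week_index`,
#'   `answer_date`, one grade column per symptom.
#' @param plans Follow-up plan tibble ([follow_up_plan()]).
#' @param surveys Experience-survey tibble (`patient_id` plus one column per
#'   survey question), or `NULL`.
#' @param etiologies Alert etiology annotations (`patient_id`, `week_index`,
#'   `etiology`), or `NULL`.
#' @return An object of class `epro_cohort`.
#' @export
epro_cohort <- function(patients, responses, plans, surveys = NULL,
                        etiologies = NULL) {
  cohort <- structure(
    list(
      patients = tibble::as_tibble(patients),
      responses = tibble::as_tibble(responses),
      plans = tibble::as_tibble(plans),
      surveys = if (!is.null(surveys)) tibble::as_tibble(surveys),
      etiologies = if (!is.null(etiologies)) tibble::as_tibble(etiologies)
    ),
    class = "epro_cohort"
  )
  validate_cohort(cohort)
}

validate_cohort <- function(cohort) {
  pts <- cohort$patients
  resp <- cohort$responses
  if (anyDuplicated(pts$patient_id)) rlang::abort("duplicate patient_id in registry")
  bad <- setdiff(resp$patient_id, pts$patient_id)
  if (length(bad) > 0) {
    row <- which(resp$patient_id %in% bad)[1]
    rlang::abort(paste0("responses row ", row, ": unknown patient '",
                        resp$patient_id[row], "'"),
                 class = "epro_load_error")
  }
  bad_ben <- setdiff(stats::na.omit(pts$benefit), c("CR", "PR", "SD", "PD"))
  if (length(bad_ben) > 0) {
    rlang::abort("benefit labels must be CR, PR, SD, PD or NA")
  }
  miss <- setdiff(epro_symptoms, names(resp))
  if (length(miss) > 0) {
    rlang::abort(paste0("responses lack grade column(s): ", paste(miss, collapse = ", ")),
                 class = "epro_load_error")
  }
  # responses must fall inside the patient's plan window
  joined <- dplyr::inner_join(resp, cohort$plans, by = "patient_id")
  out_of_window <- joined$answer_date < joined$start_date |
    joined$answer_date > joined$end_date
  if (any(out_of_window)) {
    rlang::abort(paste0("response dated outside the patient's follow-up window (row ",
                        which(out_of_window)[1], ")"),
                 class = "epro_load_error")
  }
  if (!is.null(cohort$surveys)) {
    orphan <- setdiff(cohort$surveys$patient_id, pts$patient_id)
    if (length(orphan) > 0) {
      rlang::abort("survey row references unknown patient", class = "epro_load_error")
    }
  }
  cohort
}

#' @export
print.epro_cohort <- function(x, ...) {
  cat("<epro_cohort>\n")
  cat("  patients: ", nrow(x$patients), "\n", sep = "")
  cat("  graded questionnaires: ", nrow(x$responses), "\n", sep = "")
  if (!is.null(x$surveys)) cat("  survey records: ", nrow(x$surveys), "\n", sep = "")
  ben <- table(factor(benefit_indicator(x$patients), c(0, 1)))
  cat("  evaluable: ", sum(ben), " (benefit ", ben[["1"]], ", PD ", ben[["0"]], ")\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row cohort summary
#'
#' @param x An `epro_cohort`.
#' @param ... Unused.
#' @return One-row tibble: patient counts, questionnaire counts, benefit
#'   split and follow-up span.
#' @method glance epro_cohort
#' @export
glance.epro_cohort <- function(x, ...) {
  ben <- benefit_indicator(x$patients)
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_responses = nrow(x$responses),
    n_weekly_responses = sum(x$responses$week_index >= 1),
    n_evaluable = sum(!is.na(ben)),
    n_benefit = sum(ben == 1, na.rm = TRUE),
    n_pd = sum(ben == 0, na.rm = TRUE),
    n_surveys = if (is.null(x$surveys)) 0L else nrow(x$surveys),
    max_week = max(x$responses$week_index)
  )
}

# benefit indicator: 1 = clinical benefit (CR/PR/SD), 0 = PD, NA = not
# evaluable. This coding gives symptoms more severe under progression a
# negative correlation with benefit.
benefit_indicator <- function(patients) {
  ifelse(is.na(patients$benefit), NA_real_,
         as.numeric(patients$benefit %in% c("CR", "PR", "SD")))
}

#' Long (tidy) view of the graded responses
#'
#' @param cohort An `epro_cohort`.
#' @return Tibble with columns `patient_id`, `week_index`, `answer_date`,
#'   `symptom`, `grade`.
#' @export
responses_long <- function(cohort) {
  tidyr::pivot_longer(cohort$responses, dplyr::all_of(epro_symptoms),
                      names_to = "symptom", values_to = "grade")
}
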