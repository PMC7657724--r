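#' Follow-up plans
#'
#' Builds the per-patient follow-up plan table: a weekly questionnaire
#' prompt from `start_date` (treatment-phase entry) until `end_date` (the
#' earlier of discontinuation/progression and six months of follow-up), with
#' up to `max_reminders` daily email reminders per unanswered cycle.
#'
#' @param patient_id,start_date,end_date Vectors of equal length.
#' @param prompt_period Days between prompts (7 = weekly).
#' @param max_reminders Maximum daily reminders per cycle.
#' @return Tibble with one row per patient.
#' @export
follow_up_plan <- function(patient_id, start_date, end_date,
                           prompt_period = 7L, max_reminders = 6L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (any(end_date < start_date)) rlang::abort("end_date must be >= start_date")
  if (max_reminders < 0) rlang::abort("max_reminders must be >= 0")
  tibble::tibble(
    patient_id = patient_id,
    start_date = start_date,
    end_date = end_date,
    prompt_period = as.integer(prompt_period),
    max_reminders = as.integer(max_reminders)
  )
}

#' Notification event stream for one patient
#'
#' Generates the prompt/reminder email events implied by a follow-up plan
#' and the dates the patient actually answered: one prompt per 7-day cycle;
#' if the questionnaire is not completed on the prompt day, one reminder per
#' subsequent day until the first answer in that cycle or `max_reminders`
#' is reached.
#'
#' @param plan One-row data frame as returned by [follow_up_plan()].
#' @param answer_dates Sorted `Date` vector of the patient's completed
#'   questionnaires, all within the plan window.
#' @return Tibble with columns `patient_id`, `cycle`, `date` and
#'   `type` (`"prompt"` or `"reminder"`).
#' @export
build_notification_schedule <- function(plan, answer_dates = as.Date(character())) {
  answer_dates <- as.Date(answer_dates)
  if (is.unsorted(answer_dates)) {
    rlang::abort("answer_dates must be sorted", class = "epro_validation_error")
  }
  if (length(answer_dates) > 0 &&
      (min(answer_dates) < plan$start_date || max(answer_dates) > plan$end_date)) {
    rlang::abort("answer_dates must lie within the plan window",
                 class = "epro_validation_error")
  }
  prompt_dates <- seq(plan$start_date, plan$end_date, by = plan$prompt_period)
  events <- purrr::map(seq_along(prompt_dates), function(k) {
    prompt <- prompt_dates[k]
    cycle_end <- prompt + plan$prompt_period - 1L
    in_cycle <- answer_dates[answer_dates >= prompt & answer_dates <= cycle_end]
    if (length(in_cycle) > 0 && min(in_cycle) == prompt) {
      n_rem <- 0L
    } else if (length(in_cycle) > 0) {
      n_rem <- min(as.integer(min(in_cycle) - prompt), plan$max_reminders)
    } else {
      n_rem <- plan$max_reminders
    }
    dates <- prompt + 0:n_rem
    dates <- dates[dates <= plan$end_date]
    tibble::tibble(
      cycle = k,
      date = dates,
      type = c("prompt", rep("reminder", length(dates) - 1L))
    )
  })
  dplyr::bind_rows(events) |>
    dplyr::mutate(patient_id = plan$patient_id, .before = 1)
}

# Week w (1-based) covers days [7*(w-1), 7*w) after the patient's start
# date; a patient is active in week w when the plan window overlaps any of
# those days.
active_in_week <- function(plans, week_index) {
  span <- as.integer(plans$end_date - plans$start_date)
  7L * (week_index - 1L) <= span
}

#' Weekly compliance of a cohort
#'
#' Mean number of answered symptom questionnaires per active patient per
#' week. A patient is active in week `w` when their follow-up window covers
#' any day of that (patient-relative) week; patients whose window does not
#' cover the week are excluded from the denominator. Values above 1 occur
#' when patients answer more than once in a week. The baseline questionnaire
#' (week 0) is excluded.
#'
#' @param responses Data frame of answered questionnaires with `patient_id`
#'   and `week_index`.
#' @param plans Follow-up plan table ([follow_up_plan()]).
#' @param weeks Integer weeks (>= 1) to evaluate; defaults to all weeks any
#'   plan covers.
#' @return Tibble with columns `week`, `n_active`, `n_responses`, `mean`
#'   (`NA` for weeks with an empty active set).
#' @export
compute_compliance <- function(responses, plans, weeks = NULL) {
  if (is.null(weeks)) {
    max_week <- max((as.integer(plans$end_date - plans$start_date)) %/% 7L) + 1L
    weeks <- seq_len(max_week)
  }
  if (any(weeks < 1)) rlang::abort("weeks must be >= 1")
  counts <- responses |>
    dplyr::filter(.data$week_index >= 1) |>
    dplyr::count(.data$week_index)
  purrr::map_dfr(weeks, function(w) {
    n_active <- sum(active_in_week(plans, w))
    n_resp <- sum(counts$n[counts$week_index == w])
    tibble::tibble(
      week = w,
      n_active = n_active,
      n_responses = n_resp,
      mean = if (n_active == 0) NA_real_ else n_resp / n_active
    )
  })
}

#' Range of a compliance series
#'
#' @param series Compliance tibble from [compute_compliance()], or a numeric
#'   vector of weekly means.
#' @return Named numeric vector `c(min = , max = )` over defined weeks.
#' @export
compliance_range <- function(series) {
  means <- if (is.data.frame(series)) series$mean else as.numeric(series)
  means <- means[!is.na(means)]
  if (length(means) == 0) rlang::abort("compliance series is empty")
  c(min = min(means), max = max(means))
}
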