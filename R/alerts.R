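#' Alert rule configuration
#'
#' Preset limits of the urgency algorithm: a questionnaire alerts on a
#' symptom when its current grade reaches `absolute_threshold`, or when it
#' jumps from `jump_from` in the reference (most recent prior) questionnaire
#' to at least `jump_to` now. The defaults encode "presence of a grade 3 or
#' higher symptom or increase in symptom severity from grade 0 to 2".
#'
#' @param absolute_threshold Grade that alerts regardless of history (1-4).
#' @param jump_from Reference grade of the jump rule.
#' @param jump_to Minimum current grade of the jump rule (> `jump_from`).
#' @return A list of class `epro_alert_config`.
#' @export
alert_config <- function(absolute_threshold = 3L, jump_from = 0L, jump_to = 2L) {
  if (absolute_threshold < 1 || absolute_threshold > 4) {
    rlang::abort("absolute_threshold must be in 1..4")
  }
  if (jump_to <= jump_from) rlang::abort("jump_to must exceed jump_from")
  structure(
    list(
      absolute_threshold = as.integer(absolute_threshold),
      jump_from = as.integer(jump_from),
      jump_to = as.integer(jump_to)
    ),
    class = "epro_alert_config"
  )
}

#' Evaluate the urgency algorithm for one graded questionnaire
#'
#' @param current Named integer vector (or one-row data frame slice) of the
#'   current grades per symptom.
#' @param reference Grades of the same patient's most recent prior
#'   questionnaire, or `NULL` when none exists. With no prior questionnaire
#'   the implicit reference grade is 0, so a first report at `jump_to` or
#'   above alerts (a conservative, patient-safe default).
#' @param config An [alert_config()].
#' @return Tibble with one row per triggering symptom and columns `symptom`
#'   and `reason` (`"absolute"` or `"jump"`); zero rows when nothing triggers.
#' @export
evaluate_alert <- function(current, reference = NULL, config = alert_config()) {
  if (is.data.frame(current) && is.data.frame(reference)) {
    if ("patient_id" %in% names(current) && "patient_id" %in% names(reference) &&
        !identical(current$patient_id, reference$patient_id)) {
      rlang::abort("reference questionnaire belongs to a different patient",
                   class = "epro_ordering_error")
    }
    if ("answer_date" %in% names(current) && "answer_date" %in% names(reference) &&
        reference$answer_date > current$answer_date) {
      rlang::abort("reference questionnaire is dated after the current one",
                   class = "epro_ordering_error")
    }
  }
  keep <- function(x) {
    if (is.data.frame(x)) x <- x[intersect(epro_symptoms, names(x))]
    x
  }
  current <- unlist(keep(current))
  if (!is.null(reference)) reference <- unlist(keep(reference))
  symptoms <- names(current)
  ref <- if (is.null(reference)) {
    rlang::set_names(rep(0L, length(symptoms)), symptoms)
  } else {
    unlist(reference)[symptoms]
  }
  absolute <- current >= config$absolute_threshold
  jump <- !absolute & ref == config$jump_from & current >= config$jump_to
  tibble::tibble(
    symptom = c(symptoms[absolute], symptoms[jump]),
    reason = c(rep("absolute", sum(absolute)), rep("jump", sum(jump)))
  )
}

#' Evaluate alerts for a whole table of graded questionnaires
#'
#' Orders each patient's questionnaires by `week_index` then `answer_date`,
#' takes the immediately preceding questionnaire as the jump-rule reference
#' (implicit grade 0 before the first), and applies the urgency rules to
#' every row. One decision is produced per questionnaire; a single
#' questionnaire may trigger on several symptoms.
#'
#' @param graded Data frame of graded questionnaires: `patient_id`,
#'   `week_index`, `answer_date`, plus one grade column per symptom.
#' @param config An [alert_config()].
#' @param symptoms Symptom columns to consider; defaults to the tracked 18.
#' @return Tibble with columns `patient_id`, `week_index`, `answer_date`,
#'   `triggered`, `triggers` (list-column of per-symptom trigger tibbles),
#'   `triggering_symptoms` (semicolon-joined `symptom:reason` string) and
#'   `etiology` (`NA` until annotated).
#' @export
evaluate_alerts <- function(graded, config = alert_config(), symptoms = epro_symptoms) {
  graded <- dplyr::arrange(tibble::as_tibble(graded), .data$patient_id,
                           .data$week_index, .data$answer_date)
  missing <- setdiff(symptoms, names(graded))
  if (length(missing) > 0) {
    rlang::abort(paste0("graded table lacks grade column(s): ",
                        paste(missing, collapse = ", ")))
  }
  g <- as.matrix(graded[symptoms])
  pid <- graded$patient_id
  n <- nrow(g)
  ref <- matrix(0L, n, length(symptoms), dimnames = list(NULL, symptoms))
  if (n > 1) {
    same_patient <- pid[-1] == pid[-n]
    ref[which(same_patient) + 1L, ] <- g[which(same_patient), ]
  }
  absolute <- g >= config$absolute_threshold
  jump <- !absolute & ref == config$jump_from & g >= config$jump_to
  triggers <- purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      symptom = c(symptoms[absolute[i, ]], symptoms[jump[i, ]]),
      reason = c(rep("absolute", sum(absolute[i, ])), rep("jump", sum(jump[i, ])))
    )
  })
  tibble::tibble(
    patient_id = graded$patient_id,
    week_index = graded$week_index,
    answer_date = graded$answer_date,
    triggered = rowSums(absolute | jump) > 0,
    triggers = triggers,
    triggering_symptoms = purrr::map_chr(triggers, function(tr) {
      paste(paste0(tr$symptom, ":", tr$reason), collapse = ";")
    }),
    etiology = NA_character_
  )
}

#' Annotate alert etiology
#'
#' Attaches the treating physician's etiology judgement (`"cancer"`,
#' `"treatment"` or `"unclear"`) to triggered alert decisions. Etiology is a
#' manual annotation, never inferred from the grades.
#'
#' @param decisions Alert decision tibble from [evaluate_alerts()].
#' @param labels Either a single label applied to all rows of a one-decision
#'   table, or a data frame with columns `patient_id`, `week_index` (and
#'   optionally `answer_date`) plus `etiology`.
#' @return The decisions tibble with `etiology` filled in. Re-annotation
#'   with the same label is idempotent.
#' @export
annotate_etiology <- function(decisions, labels) {
  valid <- c("cancer", "treatment", "unclear")
  if (is.character(labels) && length(labels) == 1) {
    labels <- tibble::tibble(
      patient_id = decisions$patient_id,
      week_index = decisions$week_index,
      etiology = labels
    )
  }
  if (!all(labels$etiology %in% valid)) {
    rlang::abort("etiology labels must be one of cancer, treatment, unclear")
  }
  keys <- intersect(c("patient_id", "week_index", "answer_date"), names(labels))
  labelled <- dplyr::semi_join(decisions, labels, by = keys)
  if (any(!labelled$triggered)) {
    rlang::abort("cannot annotate etiology on a non-triggered decision",
                 class = "epro_state_error")
  }
  out <- dplyr::left_join(
    decisions,
    dplyr::select(labels, dplyr::all_of(keys), new_etiology = "etiology"),
    by = keys
  )
  out$etiology <- dplyr::coalesce(out$new_etiology, out$etiology)
  dplyr::select(out, -"new_etiology")
}
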