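#' Analysis configuration
#'
#' @param window Integer vector `c(first, last)` of week indices included in
#'   an analysis (`c(1, 12)` = first 12 weeks of weekly follow-up), or
#'   `NULL` for the full follow-up including the baseline questionnaire.
#' @param effect_cutoffs Named, strictly decreasing cutoffs on `|r|` for the
#'   large / medium / small Pearson effect-size classes.
#' @param bin_width Width (weeks) of trajectory bins.
#' @return List of class `epro_analysis_config`.
#' @export
analysis_config <- function(window = NULL,
                            effect_cutoffs = c(large = 0.5, medium = 0.3, small = 0.1),
                            bin_width = 2L) {
  if (!all(diff(effect_cutoffs) < 0) || any(effect_cutoffs <= 0) ||
      any(effect_cutoffs >= 1)) {
    rlang::abort("effect_cutoffs must be strictly decreasing within (0, 1)")
  }
  structure(
    list(window = window, effect_cutoffs = effect_cutoffs,
         bin_width = as.integer(bin_width)),
    class = "epro_analysis_config"
  )
}

in_window <- function(week_index, window) {
  if (is.null(window)) rep(TRUE, length(week_index))
  else week_index >= window[1] & week_index <= window[2]
}

grade_bucket <- function(grade) {
  dplyr::case_when(grade >= 3 ~ "3-4", TRUE ~ as.character(grade))
}

#' Grade distribution per symptom
#'
#' Percentage of questionnaires in each severity bucket (0, 1, 2, 3-4) per
#' symptom, over all answered questionnaires in the window. Rows sum to 100
#' up to rounding.
#'
#' @param responses Graded questionnaire tibble (or an `epro_cohort`).
#' @param window Week window as in [analysis_config()]; `NULL` = all.
#' @return Tibble: `symptom`, `bucket`, `n`, `pct` (raw fraction * 100) and
#'   `pct_rounded` (whole percent, as printed in summary tables).
#' @export
grade_distribution <- function(responses, window = NULL) {
  if (inherits(responses, "epro_cohort")) responses <- responses$responses
  responses <- dplyr::filter(responses, in_window(.data$week_index, window))
  if (nrow(responses) == 0) rlang::abort("no responses in the analysis window")
  denom <- nrow(responses)
  tidyr::pivot_longer(responses, dplyr::all_of(epro_symptoms),
                      names_to = "symptom", values_to = "grade") |>
    dplyr::mutate(bucket = factor(grade_bucket(.data$grade),
                                  levels = c("0", "1", "2", "3-4"))) |>
    dplyr::count(.data$symptom, .data$bucket, .drop = FALSE) |>
    dplyr::mutate(pct = 100 * .data$n / denom,
                  pct_rounded = round(.data$pct))
}

#' Alert summary over a window
#'
#' Alert rate (triggered questionnaires / answered questionnaires in the
#' window), etiology counts over triggered decisions, and per-symptom
#' trigger counts. By-symptom counts can exceed the number of alerts since
#' one questionnaire may alert on several symptoms.
#'
#' @param decisions Alert decisions from [evaluate_alerts()] (annotated with
#'   etiology where available).
#' @param responses The graded questionnaires the decisions were derived
#'   from (or an `epro_cohort`).
#' @param window Week window; `NULL` = all weekly questionnaires.
#' @return List of class `epro_alert_summary`: `n_questionnaires`,
#'   `n_alerts`, `rate` (fraction), `rate_pct`, `etiology` tibble and
#'   `by_symptom` tibble.
#' @export
alert_summary <- function(decisions, responses, window = NULL) {
  if (inherits(responses, "epro_cohort")) responses <- responses$responses
  responses <- dplyr::filter(responses, .data$week_index >= 1,
                             in_window(.data$week_index, window))
  decisions <- dplyr::filter(decisions, .data$week_index >= 1,
                             in_window(.data$week_index, window))
  key <- c("patient_id", "week_index", "answer_date")
  orphans <- dplyr::anti_join(decisions, responses, by = key)
  if (nrow(orphans) > 0) {
    rlang::abort("alert decision without a matching questionnaire in the window",
                 class = "epro_consistency_error")
  }
  alerts <- dplyr::filter(decisions, .data$triggered)
  etiology <- alerts |>
    dplyr::count(etiology = dplyr::coalesce(.data$etiology, "unannotated"),
                 name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  by_symptom <- dplyr::bind_rows(alerts$triggers)
  by_symptom <- if (nrow(by_symptom) == 0) {
    tibble::tibble(symptom = character(), n = integer())
  } else {
    dplyr::count(by_symptom, .data$symptom, sort = TRUE)
  }
  structure(
    list(
      n_questionnaires = nrow(responses),
      n_alerts = nrow(alerts),
      rate = nrow(alerts) / nrow(responses),
      rate_pct = 100 * nrow(alerts) / nrow(responses),
      etiology = etiology,
      by_symptom = by_symptom
    ),
    class = "epro_alert_summary"
  )
}

#' @export
print.epro_alert_summary <- function(x, ...) {
  cat("<epro_alert_summary> ", x$n_alerts, "/", x$n_questionnaires,
      " questionnaires alerted (", sprintf("%.1f", x$rate_pct), "%)\n", sep = "")
  invisible(x)
}

# --- Pearson machinery -------------------------------------------------------

#' Pairwise Pearson correlation matrix
#'
#' Product-moment correlations over all column pairs of a numeric
#' observation table, using pairwise complete observations. Cells with fewer
#' than two complete cases or a zero-variance margin carry `NA` (an explicit
#' undefined marker, never silently 0).
#'
#' @param observations Data frame or matrix of numeric columns (one row per
#'   observation unit).
#' @return Object of class `epro_corr`: list with `r` (correlation matrix),
#'   `n` (pairwise complete-case counts) and `labels`.
#' @examples
#' pearson_matrix(data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)))$r
#' @export
pearson_matrix <- function(observations) {
  m <- as.matrix(observations)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) rlang::abort("need at least 2 observations")
  n <- crossprod(!is.na(m))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = "pearson"))
  r[n < 2] <- NA_real_
  structure(list(r = r, n = n, labels = colnames(m)), class = "epro_corr")
}

#' @export
print.epro_corr <- function(x, ...) {
  cat("<epro_corr> ", length(x$labels), " variables\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a correlation matrix
#'
#' @param x An `epro_corr`.
#' @param ... Unused.
#' @return Long tibble: `var1`, `var2`, `r`, `n`, `effect_size`.
#' @method tidy epro_corr
#' @export
tidy.epro_corr <- function(x, ...) {
  tibble::tibble(
    var1 = rep(x$labels, times = length(x$labels)),
    var2 = rep(x$labels, each = length(x$labels)),
    r = as.vector(x$r),
    n = as.vector(x$n)
  ) |>
    dplyr::mutate(effect_size = purrr::map_chr(.data$r, function(r) {
      if (is.na(r)) NA_character_ else effect_size_class(r)
    }))
}

#' Effect-size class of a correlation
#'
#' Classifies `|r|` against the conventional cutoffs (large 0.5, medium 0.3,
#' small 0.1); boundary values belong to the stronger class.
#'
#' @param r Pearson correlation, `|r| <= 1`, not `NA`.
#' @param cutoffs Named decreasing cutoffs as in [analysis_config()].
#' @return One of `"large"`, `"medium"`, `"small"`, `"negligible"`.
#' @examples
#' effect_size_class(-0.41) # "medium"
#' effect_size_class(0.23)  # "small"
#' @export
effect_size_class <- function(r, cutoffs = c(large = 0.5, medium = 0.3, small = 0.1)) {
  if (length(r) != 1 || is.na(r)) {
    rlang::abort("r must be a defined correlation", class = "epro_validation_error")
  }
  if (abs(r) > 1) rlang::abort("|r| must be <= 1")
  a <- abs(r)
  if (a >= cutoffs[["large"]]) "large"
  else if (a >= cutoffs[["medium"]]) "medium"
  else if (a >= cutoffs[["small"]]) "small"
  else "negligible"
}

#' Per-questionnaire or per-patient symptom observation table
#'
#' Builds the observation table behind the correlation heatmaps. With
#' `unit = "questionnaire"` each answered questionnaire contributes one row
#' of 18 grades; with `unit = "patient"` each patient contributes one row of
#' per-symptom mean grades over the window, plus the clinical-benefit
#' indicator (1 = CR/PR/SD, 0 = PD) when available.
#'
#' @param cohort An `epro_cohort`.
#' @param window Week window; `NULL` = all.
#' @param unit `"questionnaire"` or `"patient"`.
#' @param include_benefit Add the benefit indicator column (patient unit).
#' @return Tibble of numeric columns.
#' @export
symptom_observations <- function(cohort, window = NULL,
                                 unit = c("questionnaire", "patient"),
                                 include_benefit = (unit == "patient")) {
  unit <- match.arg(unit)
  resp <- dplyr::filter(cohort$responses, in_window(.data$week_index, window))
  if (unit == "questionnaire") {
    return(resp[epro_symptoms])
  }
  means <- resp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(epro_symptoms), mean),
                     .groups = "drop")
  pts <- dplyr::mutate(cohort$patients, benefit_ind = benefit_indicator(cohort$patients))
  out <- dplyr::left_join(means, pts[c("patient_id", "benefit_ind")], by = "patient_id")
  if (isTRUE(include_benefit)) {
    dplyr::select(dplyr::rename(out, benefit = "benefit_ind"), -"patient_id")
  } else {
    dplyr::select(out, -"patient_id", -"benefit_ind")
  }
}

#' Correlation between each symptom and clinical benefit
#'
#' One observation per evaluable patient: the benefit indicator
#' (1 = CR/PR/SD, 0 = PD) against the patient's mean grade of the symptom
#' over the window. Patients not evaluated for response are excluded.
#'
#' @param cohort An `epro_cohort`.
#' @param window Week window; `NULL` = all.
#' @param cutoffs Effect-size cutoffs.
#' @return Tibble: `symptom`, `r`, `n`, `effect_size` (`NA` r for
#'   zero-variance symptoms).
#' @export
benefit_correlation <- function(cohort, window = NULL,
                                cutoffs = c(large = 0.5, medium = 0.3, small = 0.1)) {
  pts <- cohort$patients
  ben <- benefit_indicator(pts)
  if (sum(ben == 1, na.rm = TRUE) < 1 || sum(ben == 0, na.rm = TRUE) < 1) {
    rlang::abort("need evaluable patients in both benefit classes")
  }
  resp <- dplyr::filter(cohort$responses, in_window(.data$week_index, window))
  means <- resp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(epro_symptoms), mean),
                     .groups = "drop")
  obs <- dplyr::inner_join(
    tibble::tibble(patient_id = pts$patient_id, benefit = ben),
    means, by = "patient_id"
  ) |>
    dplyr::filter(!is.na(.data$benefit))
  purrr::map_dfr(epro_symptoms, function(s) {
    x <- obs[[s]]
    r <- if (stats::sd(x) == 0 || stats::sd(obs$benefit) == 0) {
      NA_real_
    } else {
      stats::cor(obs$benefit, x)
    }
    tibble::tibble(
      symptom = s, r = r, n = nrow(obs),
      effect_size = if (is.na(r)) NA_character_ else effect_size_class(r, cutoffs)
    )
  })
}

#' Mean symptom grade per 2-week bin
#'
#' Average reported grade of a symptom over all answered questionnaires of
#' the group's patients, binned in `bin_width`-week intervals of the weekly
#' follow-up. Empty bins are `NA`.
#'
#' @param cohort An `epro_cohort`.
#' @param symptom Symptom id.
#' @param group `"all"`, `"benefit"` (CR/PR/SD) or `"PD"`.
#' @param window Week window; default first 12 weeks.
#' @param bin_width Bin width in weeks.
#' @return Tibble: `bin`, `week_from`, `week_to`, `n`, `mean_grade`.
#' @export
binned_average_grade <- function(cohort, symptom, group = c("all", "benefit", "PD"),
                                 window = c(1, 12), bin_width = 2L) {
  group <- match.arg(group)
  if (!symptom %in% epro_symptoms) rlang::abort(paste0("unknown symptom '", symptom, "'"))
  ben <- benefit_indicator(cohort$patients)
  keep_ids <- switch(group,
    all = cohort$patients$patient_id[!is.na(ben)],
    benefit = cohort$patients$patient_id[!is.na(ben) & ben == 1],
    PD = cohort$patients$patient_id[!is.na(ben) & ben == 0]
  )
  starts <- seq(window[1], window[2], by = bin_width)
  resp <- dplyr::filter(cohort$responses, .data$patient_id %in% keep_ids,
                        in_window(.data$week_index, window))
  purrr::map_dfr(seq_along(starts), function(b) {
    lo <- starts[b]
    hi <- min(starts[b] + bin_width - 1L, window[2])
    g <- resp[[symptom]][resp$week_index >= lo & resp$week_index <= hi]
    tibble::tibble(
      bin = b, week_from = lo, week_to = hi, n = length(g),
      mean_grade = if (length(g) == 0) NA_real_ else mean(g)
    )
  })
}

#' Per-arm symptom prevalence
#'
#' Fraction of evaluable patients in each benefit arm who reported the
#' symptom at grade >= 1 at least once in the window.
#'
#' @param cohort An `epro_cohort`.
#' @param symptom Symptom id.
#' @param window Week window; `NULL` = full follow-up.
#' @return Tibble: `arm` (benefit/PD), `n_reporting`, `n_patients`,
#'   `prevalence` (fraction; `NA` for an empty arm).
#' @export
prevalence_by_arm <- function(cohort, symptom, window = NULL) {
  if (!symptom %in% epro_symptoms) rlang::abort(paste0("unknown symptom '", symptom, "'"))
  ben <- benefit_indicator(cohort$patients)
  resp <- dplyr::filter(cohort$responses, in_window(.data$week_index, window))
  reporters <- unique(resp$patient_id[resp[[symptom]] >= 1])
  purrr::map_dfr(c(benefit = 1, PD = 0), function(code) {
    ids <- cohort$patients$patient_id[!is.na(ben) & ben == code]
    tibble::tibble(
      n_reporting = sum(ids %in% reporters),
      n_patients = length(ids),
      prevalence = if (length(ids) == 0) NA_real_ else mean(ids %in% reporters)
    )
  }, .id = "arm")
}

# --- experience survey -------------------------------------------------------

#' Fixed experience-survey instrument
#'
#' The six patient-experience questions and their closed answer options.
#'
#' @return Named list: question id -> character vector of valid options.
#' @export
survey_questions <- function() {
  list(
    ease_of_use = c("very_easy", "easy", "difficult", "very_difficult", "cannot_say"),
    needed_help = c("yes", "no"),
    questions_understandable = c("totally_agree", "partly_agree", "partly_disagree",
                                 "totally_disagree", "cannot_say"),
    improved_follow_up = c("yes", "no", "cannot_say"),
    benefited = c("yes", "no", "cannot_say"),
    would_recommend = c("yes", "no", "cannot_say")
  )
}

#' Experience-survey answer counts and percentages
#'
#' @param surveys Survey tibble (`patient_id` + one column per question), or
#'   an `epro_cohort`.
#' @return Tibble: `question`, `answer`, `n`, `pct`, `pct_rounded`;
#'   percentages per question sum to 100 up to rounding.
#' @export
survey_summary <- function(surveys) {
  if (inherits(surveys, "epro_cohort")) surveys <- surveys$surveys
  qs <- survey_questions()
  miss <- setdiff(names(qs), names(surveys))
  if (length(miss) > 0) {
    rlang::abort(paste0("survey records must answer all 6 questions; missing: ",
                        paste(miss, collapse = ", ")),
                 class = "epro_validation_error")
  }
  purrr::imap_dfr(qs, function(options, q) {
    a <- surveys[[q]]
    bad <- setdiff(unique(a), options)
    if (length(bad) > 0) {
      rlang::abort(paste0(q, ": unknown answer option '", bad[1], "'"),
                   class = "epro_validation_error")
    }
    counts <- table(factor(a, levels = options))
    tibble::tibble(
      question = q,
      answer = names(counts),
      n = as.integer(counts),
      pct = 100 * as.integer(counts) / length(a),
      pct_rounded = round(100 * as.integer(counts) / length(a))
    )
  })
}
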