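#' Default per-symptom weekly dynamics
#'
#' Target steady-state weekly prevalence (fraction of weeks a symptom is
#' present) and week-to-week persistence of the two-state presence chain,
#' per symptom. Prevalences track the observed per-questionnaire positivity
#' of each symptom in anti-PD-(L)1 cohorts (fatigue most common, visible
#' bleeding essentially absent); persistence reflects that these symptoms
#' run over weeks rather than days.
#'
#' @return Tibble: `symptom`, `prevalence`, `persistence`.
#' @export
default_symptom_dynamics <- function() {
  tibble::tribble(
    ~symptom,              ~prevalence, ~persistence,
    "blood_in_stool",      0.005,       0.3,
    "hematuria",           0.005,       0.3,
    "blurred_vision",      0.04,        0.5,
    "chest_pain",          0.06,        0.5,
    "cough",               0.27,        0.7,
    "loss_of_appetite",    0.21,        0.6,
    "diarrhea",            0.04,        0.4,
    "dizziness",           0.08,        0.5,
    "fatigue",             0.40,        0.7,
    "fever",               0.05,        0.3,
    "headache",            0.13,        0.5,
    "itching",             0.18,        0.6,
    "nausea",              0.21,        0.6,
    "pain_in_joints",      0.20,        0.7,
    "rash",                0.12,        0.6,
    "shortness_of_breath", 0.17,        0.6,
    "stomach_pain",        0.06,        0.5,
    "vomiting",            0.02,        0.3
  )
}

#' Simulation parameters
#'
#' Parameters of the synthetic-cohort generator. Defaults encode the study
#' conditions of a 37-patient anti-PD-(L)1 feasibility cohort: tumor mix
#' 15 lung : 9 melanoma : 9 genitourinary : 4 head-and-neck, clinical
#' benefit probability 22/34, 24 weeks of weekly follow-up with 6 daily
#' reminders per unanswered cycle.
#'
#' @param n_patients Number of simulated patients.
#' @param tumor_mix Named probabilities over the four tumor types (sum 1).
#' @param p_benefit Probability a patient's best response is CR/PR/SD
#'   (vs PD).
#' @param symptom_dynamics Tibble as [default_symptom_dynamics()]: weekly
#'   steady-state prevalence and persistence per symptom. Weekly onset
#'   probability is derived as `prevalence * (1 - persistence) /
#'   (1 - prevalence)`.
#' @param severity_probs Probabilities of grades 1-4 given a symptom is
#'   present (capped at each symptom's `max_grade`).
#' @param itching_benefit_odds Multiplier on the weekly itching onset odds
#'   for benefit patients (> 1 makes itching more prevalent under benefit).
#' @param chest_pain_pd_drift Additive weekly drift (grade units/week) of
#'   the mean chest-pain grade for PD patients while the symptom is present.
#' @param p_prompt_answer Probability of answering on the prompt day.
#' @param reminder_hazard Daily probability of answering on each of the 6
#'   reminder days, given still unanswered.
#' @param follow_up_weeks Weeks of weekly follow-up (24 = six months).
#' @param seed Integer seed; `simulate_cohort()` is fully reproducible
#'   given the seed.
#' @return List of class `epro_sim_params`.
#' @export
sim_params <- function(n_patients = 37L,
                       tumor_mix = c(lung = 15, melanoma = 9,
                                     genitourinary = 9, head_and_neck = 4) / 37,
                       p_benefit = 22 / 34,
                       symptom_dynamics = default_symptom_dynamics(),
                       severity_probs = c(0.65, 0.25, 0.08, 0.02),
                       itching_benefit_odds = 3,
                       chest_pain_pd_drift = 0.04,
                       p_prompt_answer = 0.7,
                       reminder_hazard = 0.15,
                       follow_up_weeks = 24L,
                       seed = 1L) {
  probs <- c(tumor_mix, p_benefit, symptom_dynamics$prevalence,
             symptom_dynamics$persistence, severity_probs,
             p_prompt_answer, reminder_hazard)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("all probabilities must lie in [0, 1]",
                 class = "epro_validation_error")
  }
  if (abs(sum(tumor_mix) - 1) > 1e-8) {
    rlang::abort("tumor_mix must sum to 1", class = "epro_validation_error")
  }
  if (abs(sum(severity_probs) - 1) > 1e-8) {
    rlang::abort("severity_probs must sum to 1", class = "epro_validation_error")
  }
  if (!setequal(symptom_dynamics$symptom, epro_symptoms)) {
    rlang::abort("symptom_dynamics must cover the 18 tracked symptoms")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), tumor_mix = tumor_mix,
      p_benefit = p_benefit, symptom_dynamics = symptom_dynamics,
      severity_probs = severity_probs,
      itching_benefit_odds = itching_benefit_odds,
      chest_pain_pd_drift = chest_pain_pd_drift,
      p_prompt_answer = p_prompt_answer, reminder_hazard = reminder_hazard,
      follow_up_weeks = as.integer(follow_up_weeks), seed = as.integer(seed)
    ),
    class = "epro_sim_params"
  )
}

#' Expected per-cycle answer probability
#'
#' Probability that a weekly cycle is answered at all under the prompt +
#' 6-reminder adherence model; the cohort compliance of a simulated cohort
#' concentrates around this value.
#'
#' @param params An [sim_params()] object.
#' @return Scalar probability.
#' @export
expected_answer_prob <- function(params) {
  params$p_prompt_answer +
    (1 - params$p_prompt_answer) * (1 - (1 - params$reminder_hazard)^6)
}

#' Simulate a synthetic cohort
#'
#' Generates a cohort with the longitudinal, benefit-linked structure the
#' analysis pipeline assumes. Per patient: a benefit label drawn with
#' `p_benefit`; per symptom, a two-state weekly presence Markov chain
#' (initialised at its stationary distribution) with onset/persistence from
#' `symptom_dynamics`; a categorical severity draw when present; benefit
#' effects (itching onset odds multiplied for benefit patients; PD
#' patients' chest-pain grade mean drifting up linearly in week); and a
#' prompt/reminder adherence model deciding which weekly questionnaires
#' exist. Fully reproducible given `params$seed`.
#'
#' @param params An [sim_params()] object.
#' @return An [epro_cohort()].
#' @export
simulate_cohort <- function(params = sim_params()) {
  set.seed(params$seed)
  n <- params$n_patients
  weeks <- params$follow_up_weeks
  start <- as.Date("2020-01-06")

  ids <- sprintf("SIM%04d", seq_len(n))
  benefit_ind <- stats::rbinom(n, 1, params$p_benefit)
  best_resp <- ifelse(benefit_ind == 1,
                      sample(c("CR", "PR", "SD"), n, replace = TRUE,
                             prob = c(0.1, 0.35, 0.55)),
                      "PD")
  patients <- tibble::tibble(
    patient_id = ids,
    age = sample(32:80, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(27, 10) / 37),
    tumor_type = sample(names(params$tumor_mix), n, replace = TRUE,
                        prob = params$tumor_mix),
    stage = sample(c("III", "IV"), n, replace = TRUE, prob = c(9, 28) / 37),
    ecog = sample(0:2, n, replace = TRUE, prob = c(20, 15, 2) / 37),
    benefit = best_resp
  )
  plans <- follow_up_plan(ids, rep(start, n), rep(start + 7L * weeks - 1L, n))

  # adherence: week 0 baseline always answered; each later cycle answered on
  # the prompt day, on a reminder day, or not at all
  offsets <- matrix(NA_integer_, n, weeks)
  prompt_hit <- matrix(stats::runif(n * weeks) < params$p_prompt_answer, n, weeks)
  offsets[prompt_hit] <- 0L
  for (d in 1:6) {
    open <- is.na(offsets)
    hit <- open & matrix(stats::runif(n * weeks) < params$reminder_hazard, n, weeks)
    offsets[hit] <- d
  }

  # per-symptom presence chains and grades over weeks 0..weeks
  max_grades <- purrr::map_int(default_symptom_catalog(), "max_grade")
  dyn <- params$symptom_dynamics
  grades <- list()
  for (i in seq_len(nrow(dyn))) {
    s <- dyn$symptom[i]
    pers <- dyn$persistence[i]
    prev <- dyn$prevalence[i]
    onset <- if (prev >= 1) 1 else prev * (1 - pers) / (1 - prev)
    onset_vec <- rep(onset, n)
    prev_vec <- rep(prev, n)
    if (s == "itching" && params$itching_benefit_odds != 1) {
      odds <- onset / max(1 - onset, 1e-12) * params$itching_benefit_odds
      onset_b <- odds / (1 + odds)
      onset_vec <- ifelse(benefit_ind == 1, onset_b, onset)
      prev_vec <- onset_vec / (onset_vec + 1 - pers)
    }
    state <- matrix(0L, n, weeks + 1L)
    state[, 1] <- stats::rbinom(n, 1, prev_vec)
    for (w in seq_len(weeks)) {
      p <- ifelse(state[, w] == 1, pers, onset_vec)
      state[, w + 1] <- stats::rbinom(n, 1, p)
    }
    g <- matrix(0L, n, weeks + 1L)
    present <- which(state == 1)
    if (length(present) > 0) {
      g[present] <- sample(1:4, length(present), replace = TRUE,
                           prob = params$severity_probs)
    }
    if (s == "chest_pain" && params$chest_pain_pd_drift != 0) {
      # drift acts on the unconditional weekly grade of PD patients: a
      # nonzero bump also makes the symptom present, so both prevalence and
      # mean grade rise linearly with week under progression
      wk <- matrix(rep(0:weeks, each = n), n, weeks + 1L)
      bump <- matrix(stats::rpois(n * (weeks + 1L),
                                  params$chest_pain_pd_drift * wk), n, weeks + 1L)
      pd <- benefit_ind == 0
      g[pd, ] <- g[pd, ] + bump[pd, , drop = FALSE]
    }
    grades[[s]] <- pmin(g, max_grades[[s]])
  }

  answered <- cbind(TRUE, !is.na(offsets)) # col 1 = baseline week 0
  idx <- which(answered, arr.ind = TRUE)
  wk0 <- idx[, 2] - 1L # week index (0 = baseline)
  day_offset <- ifelse(wk0 == 0, 0L, offsets[cbind(idx[, 1], pmax(wk0, 1L))])
  responses <- tibble::tibble(
    patient_id = ids[idx[, 1]],
    week_index = as.integer(wk0),
    answer_date = start + ifelse(wk0 == 0, 0L, 7L * (wk0 - 1L) + day_offset)
  )
  for (s in epro_symptoms) {
    responses[[s]] <- grades[[s]][cbind(idx[, 1], idx[, 2])]
  }
  responses <- dplyr::arrange(responses, .data$patient_id, .data$week_index)

  surveys <- tibble::tibble(patient_id = ids)
  for (q in names(survey_questions())) {
    opts <- survey_questions()[[q]]
    probs <- fixture_survey_counts()[[q]]
    surveys[[q]] <- sample(names(probs), n, replace = TRUE, prob = probs)
  }

  epro_cohort(patients, responses, plans, surveys)
}
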