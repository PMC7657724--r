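# Independent encoding of the NCI-CTCAE v4.03 criteria behind the 18
# patient-reportable symptom gradings, written as plain nested conditionals
# (deliberately not sharing code or structure with the package's declarative
# rule engine). Serves as the oracle for exhaustive rule-table sweeps.

ctcae_oracle_grade <- function(symptom, a) {
  if (!isTRUE(a$present)) return(0L)
  adl3 <- function() {
    if (isTRUE(a$limits_self_care)) 3L
    else if (isTRUE(a$limits_instrumental_adl)) 2L
    else 1L
  }
  switch(symptom,
    blood_in_stool = {
      if (isTRUE(a$needs_urgent_care)) 4L
      else if (a$amount == "large_amounts") 3L
      else if (a$amount == "clearly_visible") 2L
      else 1L
    },
    hematuria = {
      if (isTRUE(a$needs_urgent_care)) 4L
      else if (a$appearance == "bloody_with_clots") 3L
      else if (a$appearance == "clearly_bloody") 2L
      else 1L
    },
    blurred_vision = adl3(),
    chest_pain = {
      if (isTRUE(a$limits_self_care) || isTRUE(a$pain_at_rest)) 3L
      else if (isTRUE(a$limits_instrumental_adl)) 2L
      else 1L
    },
    cough = adl3(),
    loss_of_appetite = {
      if (isTRUE(a$significant_weight_loss)) 3L
      else if (isTRUE(a$eating_less)) 2L
      else 1L
    },
    diarrhea = {
      # grade 2: increase of 4-6 stools/day over baseline; grade 3: >= 7,
      # hospitalization-level symptoms, or limiting self care
      if (isTRUE(a$hospitalization_level_symptoms) || isTRUE(a$limits_self_care) ||
          a$stools_per_day_over_baseline >= 7) 3L
      else if (a$stools_per_day_over_baseline >= 4) 2L
      else 1L
    },
    dizziness = adl3(),
    fatigue = {
      if (isTRUE(a$not_relieved_by_rest) && isTRUE(a$limits_self_care)) 3L
      else if (isTRUE(a$limits_self_care)) 2L
      else if (isTRUE(a$not_relieved_by_rest) && isTRUE(a$limits_instrumental_adl)) 2L
      else 1L
    },
    fever = {
      if (a$highest_temperature == "over_40_0") 3L
      else if (a$highest_temperature == "t_39_1_to_40_0") 2L
      else 1L
    },
    headache = adl3(),
    itching = {
      if (isTRUE(a$constant_or_limits_sleep)) 3L
      else if (isTRUE(a$widespread) || isTRUE(a$limits_instrumental_adl)) 2L
      else 1L
    },
    nausea = {
      if (isTRUE(a$barely_able_to_eat_or_drink)) 3L
      else if (isTRUE(a$eating_less)) 2L
      else 1L
    },
    pain_in_joints = adl3(),
    rash = {
      # body-surface-area thirds of the maculo-papular rash criteria
      if (a$body_area == "large_area") 3L
      else if (a$body_area == "moderate_area") 2L
      else 1L
    },
    shortness_of_breath = {
      # grade 1 moderate exertion, 2 minimal exertion, 3 at rest,
      # 4 life-threatening (urgent intervention)
      if (isTRUE(a$needs_urgent_care)) 4L
      else if (a$breathless_when == "at_rest") 3L
      else if (a$breathless_when == "minimal_exertion") 2L
      else 1L
    },
    stomach_pain = adl3(),
    vomiting = {
      # 1-2 / 3-5 / >=6 episodes per 24 h; urgent intervention = grade 4
      if (isTRUE(a$needs_urgent_intervention)) 4L
      else if (a$episodes_last_24h >= 6) 3L
      else if (a$episodes_last_24h >= 3) 2L
      else 1L
    },
    stop("oracle has no entry for symptom ", symptom)
  )
}

# a strictly "worse" neighbour of an answer point along one item, or NULL
# when the item is already at its worst level
worsen_answer <- function(def, answers, item_id) {
  item <- def$items[[item_id]]
  value <- answers[[item_id]]
  new <- switch(item$type,
    boolean = if (!isTRUE(value)) TRUE,
    category = {
      i <- match(value, item$levels)
      if (i < length(item$levels)) item$levels[[i + 1L]]
    },
    count = value + 1L
  )
  if (is.null(new)) return(NULL)
  answers[[item_id]] <- new
  answers
}
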