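# shared in-code fixtures for the unit tests

zero_grades <- function() {
  stats::setNames(as.list(rep(0L, length(epro_symptoms))), epro_symptoms)
}

# one graded questionnaire row with selected symptom grades overridden
graded_row <- function(patient_id = "A", week_index = 1L,
                       answer_date = as.Date("2020-01-06"), ...) {
  g <- utils::modifyList(zero_grades(), list(...))
  tibble::tibble(patient_id = patient_id, week_index = as.integer(week_index),
                 answer_date = answer_date, !!!g)
}

# tiny two-patient cohort builder: `grades` is a tibble of graded rows
tiny_cohort <- function(grades, benefit = c(A = "PR", B = "PD")) {
  ids <- names(benefit)
  start <- as.Date("2020-01-06")
  patients <- tibble::tibble(
    patient_id = ids, age = 60, sex = "male", tumor_type = "lung",
    stage = "IV", ecog = 0L, benefit = unname(benefit)
  )
  plans <- follow_up_plan(ids, rep(start, length(ids)),
                          rep(start + 7L * 24L - 1L, length(ids)))
  epro_cohort(patients, grades, plans)
}

# complete raw answer row (all symptoms absent) for grade_responses tests
absent_raw_row <- function(patient_id = "A", week_index = 0L,
                           answer_date = as.Date("2020-01-06"),
                           catalog = default_symptom_catalog()) {
  row <- tibble::tibble(patient_id = patient_id,
                        week_index = as.integer(week_index),
                        answer_date = answer_date)
  for (def in catalog) {
    for (item_id in names(def$items)) {
      item <- def$items[[item_id]]
      null_value <- switch(item$type,
        boolean = FALSE, category = item$levels[[1]], count = 0L)
      row[[paste0(def$symptom_id, ".", item_id)]] <- null_value
    }
  }
  row
}
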