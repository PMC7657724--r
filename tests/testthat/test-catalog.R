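test_that("catalog contains the 18 tracked symptoms with valid rule tables", {
  cat18 <- default_symptom_catalog()
  expect_setequal(names(cat18), epro_symptoms)
  expect_length(cat18, 18)
  for (def in cat18) {
    expect_lte(def$max_grade, 4)
    expect_true("present" %in% names(def$items))
    grades <- vapply(def$rules, function(r) r$grade, numeric(1))
    expect_true(all(grades <= def$max_grade))
    expect_length(def$rules[[length(def$rules)]]$when, 0)
  }
})

test_that("symptom absence always grades 0 and presence grades at least 1", {
  for (s in epro_symptoms) {
    grid <- symptom_answer_grid(s)
    absent <- purrr::map(grid, 1)
    absent$present <- FALSE
    expect_identical(grade_symptom(s, absent), 0L)
    present <- purrr::map(grid, 1)
    present$present <- TRUE
    expect_gte(grade_symptom(s, present), 1L)
  }
})

test_that("worked diarrhea and vomiting gradings match CTCAE band definitions", {
  expect_identical(
    grade_symptom("diarrhea", list(
      present = TRUE, stools_per_day_over_baseline = 5L,
      hospitalization_level_symptoms = FALSE, limits_self_care = FALSE
    )),
    2L
  )
  expect_identical(
    grade_symptom("vomiting", list(
      present = TRUE, episodes_last_24h = 1L, needs_urgent_intervention = FALSE
    )),
    1L
  )
})

test_that("every answer-domain point yields exactly one in-range grade", {
  for (s in epro_symptoms) {
    def <- default_symptom_catalog()[[s]]
    grid <- symptom_answer_grid(s)
    grades <- purrr::map_int(seq_len(nrow(grid)), function(i) {
      grade_symptom(def, purrr::map(grid, i))
    })
    expect_true(all(grades >= 0 & grades <= def$max_grade), label = s)
    # deterministic: re-grading gives identical results
    again <- purrr::map_int(seq_len(nrow(grid)), function(i) {
      grade_symptom(def, purrr::map(grid, i))
    })
    expect_identical(grades, again)
  }
})

test_that("incomplete or out-of-domain answers raise named validation errors", {
  expect_error(
    grade_symptom("diarrhea", list(present = TRUE)),
    "missing item", class = "epro_validation_error"
  )
  expect_error(
    grade_symptom("fever", list(present = TRUE, highest_temperature = "boiling")),
    "fever.highest_temperature", class = "epro_validation_error"
  )
  expect_error(
    grade_symptom("vomiting", list(present = TRUE, episodes_last_24h = -1,
                                   needs_urgent_intervention = FALSE)),
    class = "epro_validation_error"
  )
})

test_that("grade_responses grades per symptom, carries identifiers, and is local", {
  raw <- absent_raw_row("P1", 3L, as.Date("2020-02-03"))
  g <- grade_responses(raw)
  expect_identical(g$patient_id, "P1")
  expect_identical(g$week_index, 3L)
  expect_identical(g$answer_date, as.Date("2020-02-03"))
  expect_true(all(unlist(g[epro_symptoms]) == 0L))

  raw2 <- raw
  raw2$nausea.present <- TRUE
  raw2$nausea.eating_less <- TRUE
  g2 <- grade_responses(raw2)
  expect_identical(g2$nausea, 2L)
  nonzero <- names(which(unlist(g2[epro_symptoms]) != 0L))
  expect_identical(nonzero, "nausea")
})

test_that("answers_for_grade round-trips through grade_symptom for all grades", {
  for (s in c("diarrhea", "vomiting", "fatigue", "shortness_of_breath", "rash")) {
    maxg <- default_symptom_catalog()[[s]]$max_grade
    for (g in 0:maxg) {
      a <- answers_for_grade(s, g)
      expect_identical(grade_symptom(s, a), as.integer(g), label = paste(s, g))
    }
  }
})

test_that("the shipped raw-answer example grades end-to-end as encoded", {
  path <- system.file("extdata", "example_responses.csv", package = "eprowatch")
  raw <- readr::read_csv(path, show_col_types = FALSE)
  g <- grade_responses(raw)
  expect_identical(nrow(g), 6L)
  ex01 <- g[g$patient_id == "EX01", ]
  expect_identical(ex01$fatigue, c(0L, 1L, 2L))
  expect_identical(ex01$diarrhea, c(0L, 0L, 2L))
  ex02 <- g[g$patient_id == "EX02", ]
  expect_identical(ex02$cough, c(1L, 3L, 0L))
  expect_identical(ex02$vomiting, c(0L, 0L, 1L))
  # grading a questionnaire is per-symptom application of grade_symptom
  expect_identical(
    unname(unlist(g[2, epro_symptoms])),
    unname(vapply(epro_symptoms, function(s) {
      items <- names(default_symptom_catalog()[[s]]$items)
      grade_symptom(s, as.list(raw[2, paste0(s, ".", items)]) |>
                      stats::setNames(items))
    }, integer(1)))
  )
})
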