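test_that("urgency rules match the preset limits on worked examples", {
  # grade 3 symptom alerts regardless of history
  tr <- evaluate_alert(graded_row(cough = 3L), graded_row(cough = 1L))
  expect_identical(tr, tibble::tibble(symptom = "cough", reason = "absolute"))
  # jump from grade 0 to 2 alerts
  tr <- evaluate_alert(graded_row(loss_of_appetite = 2L), graded_row())
  expect_identical(tr,
                   tibble::tibble(symptom = "loss_of_appetite", reason = "jump"))
  # 1 -> 2 is outside both preset limits
  expect_identical(
    nrow(evaluate_alert(graded_row(loss_of_appetite = 2L),
                        graded_row(loss_of_appetite = 1L))),
    0L
  )
  # all grades zero never alerts
  expect_identical(nrow(evaluate_alert(graded_row(), graded_row())), 0L)
})

test_that("a first questionnaire uses implicit reference grade 0", {
  expect_identical(evaluate_alert(graded_row(rash = 2L), NULL)$reason, "jump")
  expect_identical(nrow(evaluate_alert(graded_row(rash = 1L), NULL)), 0L)
})

test_that("mismatched or out-of-order reference questionnaires are rejected", {
  cur <- graded_row(patient_id = "A", week_index = 2L,
                    answer_date = as.Date("2020-01-13"))
  expect_error(
    evaluate_alert(cur, graded_row(patient_id = "B", week_index = 1L)),
    class = "epro_ordering_error"
  )
  late_ref <- graded_row(patient_id = "A", week_index = 1L,
                         answer_date = as.Date("2020-03-01"))
  expect_error(evaluate_alert(cur, late_ref), class = "epro_ordering_error")
})

test_that("evaluate_alerts produces one decision per questionnaire with all triggers", {
  graded <- dplyr::bind_rows(
    graded_row("A", 1L, as.Date("2020-01-06")),
    graded_row("A", 2L, as.Date("2020-01-13"), cough = 3L, nausea = 2L),
    graded_row("B", 1L, as.Date("2020-01-06"), fatigue = 1L)
  )
  dec <- evaluate_alerts(graded)
  expect_identical(nrow(dec), 3L)
  expect_identical(sum(dec$triggered), 1L)
  alert <- dec[dec$triggered, ]
  trig <- alert$triggers[[1]]
  expect_setequal(trig$symptom, c("cough", "nausea"))
  expect_identical(trig$reason[trig$symptom == "cough"], "absolute")
  expect_identical(trig$reason[trig$symptom == "nausea"], "jump")
  expect_identical(alert$triggering_symptoms, "cough:absolute;nausea:jump")
})

test_that("the jump rule compares against the most recent prior questionnaire", {
  graded <- dplyr::bind_rows(
    graded_row("A", 1L, as.Date("2020-01-06"), headache = 1L),
    graded_row("A", 2L, as.Date("2020-01-13"), headache = 2L) # 1 -> 2: no alert
  )
  expect_false(any(evaluate_alerts(graded)$triggered))
})

test_that("etiology annotation requires a triggered decision and is idempotent", {
  graded <- dplyr::bind_rows(
    graded_row("A", 1L, as.Date("2020-01-06"), itching = 3L),
    graded_row("B", 1L, as.Date("2020-01-06"))
  )
  dec <- evaluate_alerts(graded)
  lab <- tibble::tibble(patient_id = "A", week_index = 1L, etiology = "unclear")
  ann <- annotate_etiology(dec, lab)
  expect_identical(ann$etiology[ann$patient_id == "A"], "unclear")
  expect_true(is.na(ann$etiology[ann$patient_id == "B"]))
  expect_identical(annotate_etiology(ann, lab), ann)
  relab <- tibble::tibble(patient_id = "A", week_index = 1L, etiology = "treatment")
  expect_identical(
    annotate_etiology(ann, relab)$etiology[ann$patient_id == "A"], "treatment"
  )
  bad <- tibble::tibble(patient_id = "B", week_index = 1L, etiology = "cancer")
  expect_error(annotate_etiology(dec, bad), class = "epro_state_error")
  expect_error(
    annotate_etiology(dec, tibble::tibble(patient_id = "A", week_index = 1L,
                                          etiology = "gremlins")),
    "cancer, treatment, unclear"
  )
})

test_that("raising the current grade never un-triggers a symptom", {
  cfg <- alert_config()
  for (r in 0:4) {
    triggered_at <- vapply(0:4, function(c) {
      nrow(evaluate_alert(graded_row(fever = as.integer(c)),
                          graded_row(fever = as.integer(r)), cfg)) > 0
    }, logical(1))
    expect_true(all(diff(triggered_at) >= 0), label = paste("reference grade", r))
  }
})
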