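start <- as.Date("2020-01-06")

test_that("grade distribution buckets questionnaires and sums to 100 per symptom", {
  rows <- dplyr::bind_rows(
    graded_row("A", 1L, start, cough = 0L),
    graded_row("A", 2L, start + 7L, cough = 1L),
    graded_row("A", 3L, start + 14L, cough = 2L),
    graded_row("A", 4L, start + 21L, cough = 3L)
  )
  d <- grade_distribution(rows)
  cough <- d[d$symptom == "cough", ]
  expect_identical(cough$pct, rep(25, 4))
  sums <- d |>
    dplyr::group_by(symptom) |>
    dplyr::summarise(total = sum(pct))
  expect_true(all(abs(sums$total - 100) < 1e-9))
  # all-zero input: everything in bucket 0
  d0 <- grade_distribution(graded_row("A", 1L, start))
  expect_true(all(d0$pct[d0$bucket == "0"] == 100))
  # duplicating every record leaves percentages unchanged
  d2 <- grade_distribution(dplyr::bind_rows(rows, rows))
  expect_identical(d2$pct, d$pct)
  expect_error(grade_distribution(rows, window = c(20, 24)), "window")
})

test_that("pearson_matrix matches closed-form cases and flags undefined cells", {
  x <- c(1, 2, 3, 4)
  m <- pearson_matrix(data.frame(x = x, self = x, neg = -x, y = c(1, 3, 2, 4)))
  expect_equal(m$r["x", "self"], 1)
  expect_equal(m$r["x", "neg"], -1)
  expect_equal(m$r["x", "y"], 0.8)
  expect_true(isSymmetric(m$r))
  expect_true(all(diag(m$r) == 1))
  # zero variance and sparse pairs are undefined markers, never numbers
  m2 <- pearson_matrix(data.frame(x = x, const = rep(2, 4),
                                  holey = c(1, NA, NA, NA)))
  expect_true(is.na(m2$r["x", "const"]))
  expect_true(is.na(m2$r["x", "holey"]))
  expect_identical(m2$n["x", "holey"], 1)
  td <- tidy(m2)
  expect_identical(nrow(td), 9L)
  expect_identical(td$effect_size[td$var1 == "x" & td$var2 == "x"], "large")
})

test_that("effect-size classes use inclusive boundaries toward the stronger class", {
  expect_identical(effect_size_class(-0.41), "medium")
  expect_identical(effect_size_class(0.23), "small")
  expect_identical(effect_size_class(0.05), "negligible")
  expect_identical(effect_size_class(0.5), "large")
  expect_identical(effect_size_class(-0.3), "medium")
  expect_identical(effect_size_class(0.1), "small")
  expect_error(effect_size_class(NA_real_), class = "epro_validation_error")
  expect_error(effect_size_class(1.2))
})

test_that("alert_summary computes rate, etiologies and multi-symptom counts", {
  rows <- dplyr::bind_rows(
    graded_row("A", 1L, start),
    graded_row("A", 2L, start + 7L, cough = 3L, rash = 2L),
    graded_row("B", 1L, start, fatigue = 1L)
  )
  dec <- evaluate_alerts(rows)
  dec <- annotate_etiology(dec, tibble::tibble(patient_id = "A", week_index = 2L,
                                               etiology = "treatment"))
  s <- alert_summary(dec, rows)
  expect_identical(s$n_alerts, 1L)
  expect_equal(s$rate_pct, 100 / 3)
  expect_identical(sort(s$by_symptom$symptom), c("cough", "rash"))
  expect_identical(s$etiology$n, 1L)
  expect_identical(sum(s$etiology$n), s$n_alerts)
  # zero triggered: rate 0, empty tables
  s0 <- alert_summary(evaluate_alerts(graded_row("A", 1L, start)),
                      graded_row("A", 1L, start))
  expect_identical(s0$rate, 0)
  expect_identical(nrow(s0$by_symptom), 0L)
  # decision without a matching questionnaire
  expect_error(alert_summary(dec, rows[-2, ]), class = "epro_consistency_error")
})

test_that("benefit correlation has the sign of the arm difference", {
  rows <- dplyr::bind_rows(
    graded_row("A", 1L, start, itching = 2L),
    graded_row("A", 2L, start + 7L, itching = 1L),
    graded_row("B", 1L, start),
    graded_row("B", 2L, start + 7L, chest_pain = 2L)
  )
  co <- tiny_cohort(rows)
  bc <- benefit_correlation(co)
  expect_gt(bc$r[bc$symptom == "itching"], 0)
  expect_lt(bc$r[bc$symptom == "chest_pain"], 0)
  # benefit-independent constant grades are undefined, not zero
  expect_true(is.na(bc$r[bc$symptom == "fever"]))
  # all patients in one class is an error
  expect_error(benefit_correlation(tiny_cohort(rows, benefit = c(A = "PR", B = "SD"))),
               "both benefit classes")
})

test_that("binned average grades cover the window in 2-week bins", {
  rows <- dplyr::bind_rows(
    purrr::map(1:12, function(w) graded_row("A", w, start + 7L * (w - 1L),
                                            fatigue = 1L))
  )
  co <- tiny_cohort(rows)
  b <- binned_average_grade(co, "fatigue", "benefit")
  expect_identical(nrow(b), 6L)
  expect_true(all(b$mean_grade == 1))
  # (0, 2) within one bin averages to 1
  rows2 <- dplyr::bind_rows(
    graded_row("A", 1L, start, itching = 0L),
    graded_row("A", 2L, start + 7L, itching = 2L)
  )
  b2 <- binned_average_grade(tiny_cohort(rows2), "itching", "all")
  expect_identical(b2$mean_grade[1], 1)
  expect_true(all(is.na(b2$mean_grade[-1])))
  expect_error(binned_average_grade(co, "fatigue", "responders"))
})

test_that("prevalence by arm counts patients, not questionnaires", {
  rows <- dplyr::bind_rows(
    graded_row("A", 1L, start, rash = 1L),
    graded_row("A", 2L, start + 7L, rash = 2L), # same patient twice
    graded_row("B", 1L, start)
  )
  prev <- prevalence_by_arm(tiny_cohort(rows), "rash")
  expect_identical(prev$n_reporting[prev$arm == "benefit"], 1L)
  expect_identical(prev$prevalence[prev$arm == "PD"], 0)
  none <- prevalence_by_arm(tiny_cohort(rows), "fever")
  expect_true(all(none$prevalence == 0))
})

test_that("survey summaries count options and reject unknown answers", {
  sv <- tibble::tibble(
    patient_id = c("A", "B"),
    ease_of_use = c("easy", "very_easy"),
    needed_help = c("no", "no"),
    questions_understandable = c("totally_agree", "partly_agree"),
    improved_follow_up = c("yes", "no"),
    benefited = c("yes", "cannot_say"),
    would_recommend = c("yes", "yes")
  )
  s <- survey_summary(sv)
  imp <- s[s$question == "improved_follow_up", ]
  expect_identical(imp$pct[imp$answer %in% c("yes", "no")], c(50, 50))
  rec <- s[s$question == "would_recommend" & s$answer == "yes", ]
  expect_identical(rec$pct, 100)
  per_q <- s |>
    dplyr::group_by(question) |>
    dplyr::summarise(total = sum(pct))
  expect_true(all(abs(per_q$total - 100) < 1e-9))
  sv$needed_help[1] <- "maybe"
  expect_error(survey_summary(sv), class = "epro_validation_error")
  expect_error(survey_summary(sv[, -3]), class = "epro_validation_error")
})
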