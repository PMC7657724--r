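start <- as.Date("2020-01-06")

test_that("reminder events stop at the first answer of a cycle", {
  plan <- follow_up_plan("A", start, start + 27L) # 4 full cycles
  # answered on the prompt day: prompt only
  ev <- build_notification_schedule(plan, start)
  expect_identical(nrow(ev[ev$cycle == 1, ]), 1L)
  expect_identical(ev$type[ev$cycle == 1], "prompt")
  # unanswered cycle: prompt + 6 reminders
  expect_identical(nrow(ev[ev$cycle == 2, ]), 7L)
  expect_identical(ev$type[ev$cycle == 2], c("prompt", rep("reminder", 6)))
  # answered 3 days after the prompt: prompt + 3 reminders
  ev3 <- build_notification_schedule(plan, c(start, start + 7L + 3L))
  expect_identical(nrow(ev3[ev3$cycle == 2, ]), 4L)
})

test_that("every cycle emits between 1 and 1 + max_reminders events", {
  plan <- follow_up_plan("A", start, start + 7L * 10L - 1L)
  set.seed(11)
  for (rep in 1:20) {
    answered <- sort(start + sample(0:69, sample(0:10, 1)))
    ev <- build_notification_schedule(plan, answered)
    per_cycle <- dplyr::count(ev, cycle)
    expect_true(all(per_cycle$n >= 1 & per_cycle$n <= 7))
    expect_identical(sum(ev$type == "prompt"), 10L)
  }
})

test_that("unsorted or out-of-window answer dates are rejected", {
  plan <- follow_up_plan("A", start, start + 27L)
  expect_error(build_notification_schedule(plan, c(start + 3L, start)),
               class = "epro_validation_error")
  expect_error(build_notification_schedule(plan, start + 100L),
               class = "epro_validation_error")
})

test_that("weekly compliance is answered questionnaires over active patients", {
  plans <- follow_up_plan(c("A", "B"), rep(start, 2), rep(start + 167L, 2))
  resp1 <- dplyr::bind_rows(graded_row("A", 1L, start), graded_row("B", 1L, start))
  expect_identical(compute_compliance(resp1, plans, weeks = 1L)$mean, 1)
  # one patient answering twice: means above 1 are possible
  resp2 <- dplyr::bind_rows(resp1, graded_row("A", 1L, start + 2L))
  expect_identical(compute_compliance(resp2, plans, weeks = 1L)$mean, 1.5)
  # baseline questionnaires are excluded from the weekly series
  resp3 <- dplyr::bind_rows(resp1, graded_row("A", 0L, start))
  expect_identical(compute_compliance(resp3, plans, weeks = 1L)$mean, 1)
})

test_that("patients whose window excludes a week leave its compliance unchanged", {
  plans <- follow_up_plan(c("A", "B", "C"), rep(start, 3),
                          c(start + 167L, start + 167L, start + 6L))
  resp <- dplyr::bind_rows(graded_row("A", 3L, start + 14L),
                           graded_row("B", 3L, start + 15L))
  with_c <- compute_compliance(resp, plans, weeks = 3L)
  without_c <- compute_compliance(resp, plans[1:2, ], weeks = 3L)
  expect_identical(with_c$mean, without_c$mean)
  expect_identical(with_c$n_active, 2L)
})

test_that("an empty active-patient set yields an undefined value, not zero", {
  plans <- follow_up_plan("A", start, start + 6L) # active week 1 only
  resp <- graded_row("A", 1L, start)
  out <- compute_compliance(resp, plans, weeks = c(1L, 5L))
  expect_identical(out$mean[out$week == 1], 1)
  expect_true(is.na(out$mean[out$week == 5]))
})

test_that("compliance_range spans defined weeks and rejects empty series", {
  expect_identical(compliance_range(rep(1, 24)), c(min = 1, max = 1))
  expect_identical(compliance_range(c(0.5, 0.9, 0.7)), c(min = 0.5, max = 0.9))
  expect_error(compliance_range(numeric(0)), "empty")
  expect_error(compliance_range(c(NA_real_, NA_real_)), "empty")
})
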