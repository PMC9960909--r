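test_that("events project onto the breaths that contain them", {
  b <- tibble::tibble(
    breath = 1:3, trigger_index = c(1L, 101L, 201L),
    cycle_index = c(51L, 151L, 251L), end_index = c(101L, 201L, 301L),
    ti_s = 1, te_s = 1
  )
  ev <- pva_events("ineffective_trigger", 150)
  expect_equal(
    label_breaths(b, ev, "ineffective_trigger"),
    c(FALSE, TRUE, FALSE)
  )
  # two events in one breath: still a single positive label
  ev2 <- pva_events(rep("ineffective_trigger", 2), c(150, 160))
  expect_equal(
    label_breaths(b, ev2, "ineffective_trigger"),
    c(FALSE, TRUE, FALSE)
  )
})

test_that("stragglers are attached within tolerance, dropped beyond it", {
  b <- tibble::tibble(
    breath = 1L, trigger_index = 1L, cycle_index = 51L, end_index = 101L,
    ti_s = 1, te_s = 1
  )
  # 0.3 s past the last breath end: attached, with a warning
  near <- pva_events("double_trigger", 115)
  expect_warning(
    lab <- label_breaths(b, near, "double_trigger"),
    "attached"
  )
  expect_true(lab)
  # 2 s past: dropped
  far <- pva_events("double_trigger", 201)
  expect_warning(
    lab2 <- label_breaths(b, far, "double_trigger"),
    "dropped"
  )
  expect_false(lab2)
})

test_that("confusion cross-tabulates labels", {
  cm <- confusion(pred = c(TRUE, FALSE), gold = c(TRUE, FALSE))
  expect_equal(cm$tp, 1)
  expect_equal(cm$tn, 1)
  expect_equal(cm$fp + cm$fn, 0)
  expect_equal(confusion(TRUE, FALSE)$fp, 1)
  expect_error(confusion(c(TRUE, TRUE), TRUE), class = "ventasync_contract_error")
})

test_that("diagnostic metrics round half-up to the printed precision", {
  m <- pva_metrics(confusion_matrix(tp = 481, fp = 3, fn = 235, tn = 3777))
  expect_equal(m$sensitivity_pct, 67.18)
  expect_equal(m$specificity_pct, 99.92)
  expect_equal(m$ppv_pct, 99.38)
  expect_equal(m$npv_pct, 94.14)

  m2 <- pva_metrics(confusion_matrix(tp = 727, fp = 202, fn = 183, tn = 3384))
  expect_equal(m2$sensitivity_pct, 79.89)
  expect_equal(m2$specificity_pct, 94.37)
  expect_equal(m2$ppv_pct, 78.26)
  expect_equal(m2$npv_pct, 94.87)

  forced <- pva_metrics(confusion_matrix(tp = 1, fp = 0, fn = 1, tn = 0))
  expect_equal(forced$sensitivity_pct, 50)
  expect_equal(forced$ppv_pct, 100)
  expect_true(is.nan(forced$specificity_pct))

  allzero <- pva_metrics(confusion_matrix(0, 0, 0, 0))
  expect_true(all(is.nan(unlist(allzero))))
})

test_that("sensitivity and PPV never decrease as true positives grow", {
  ms <- purrr::map_dfr(
    c(100, 200, 400, 700),
    ~ pva_metrics(confusion_matrix(tp = .x, fp = 50, fn = 200, tn = 3000))
  )
  expect_true(all(diff(ms$sensitivity_pct) >= 0))
  expect_true(all(diff(ms$ppv_pct) >= 0))
})

test_that("evaluate_run reproduces the injection log on clean signals", {
  sim <- simulate_ventilation(
    sim_config(duration_s = 400, it_rate = 0.12, seed = 5)
  )
  ev <- evaluate_run(sim$stream, sim$gold_events)
  it <- ev$ineffective_trigger
  expect_equal(it$metrics$sensitivity_pct, 100)
  expect_equal(it$metrics$specificity_pct, 100)
  # margins: tp+fn = gold positives, tp+fp = predicted positives
  expect_equal(
    it$confusion$tp + it$confusion$fn,
    sum(sim$breath_log$type == "it_host")
  )

  # all-sub-threshold injections: nothing may be predicted positive
  sub <- simulate_ventilation(
    sim_config(duration_s = 400, it_rate = 0.12, it_amplitude_lpm = 4, seed = 5)
  )
  ev2 <- evaluate_run(sub$stream, sub$gold_events)
  expect_equal(ev2$ineffective_trigger$metrics$sensitivity_pct, 0)
  expect_equal(ev2$ineffective_trigger$metrics$specificity_pct, 100)

  expect_identical(
    tidy(evaluate_run(sim$stream, sim$gold_events)),
    tidy(ev)
  )
})

test_that("tidiers expose counts and metrics in broom shapes", {
  cm <- confusion_matrix(tp = 481, fp = 3, fn = 235, tn = 3777)
  td <- tidy(cm)
  expect_equal(td$count[td$cell == "tp"], 481)
  gl <- glance(cm)
  expect_equal(gl$n, 4496)
  expect_equal(gl$sensitivity_pct, 67.18)

  sim <- simulate_ventilation(sim_config(duration_s = 200, it_rate = 0.2, seed = 6))
  ev <- evaluate_run(sim$stream, sim$gold_events)
  td2 <- tidy(ev)
  expect_equal(nrow(td2), 2)
  expect_setequal(
    td2$event_type, c("double_trigger", "ineffective_trigger")
  )
  gl2 <- glance(ev)
  expect_equal(gl2$it_sensitivity_pct, 100)
})
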