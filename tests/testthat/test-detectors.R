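test_that("double trigger fires on Te below half the mean Ti, strictly", {
  # Te sequence: 2, 0.4, 2 s with Ti = 1 s; only the 0.4 s pair qualifies
  s <- breaths_with_te(c(2, 0.4, 2, 2))
  b <- segment_breaths(s)
  ev <- detect_double_trigger(s, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$breath_ordinal, 2L)
  expect_equal(ev$sample_index, b$cycle_index[2])
  expect_equal(ev$te_s, 0.4)
  expect_equal(ev$mean_ti_s, 1)

  # Te exactly half the mean Ti: strict inequality, no event
  s2 <- breaths_with_te(c(2, 0.5, 2, 2))
  expect_equal(nrow(detect_double_trigger(s2, segment_breaths(s2))), 0)
})

test_that("double trigger fires when volume fails to return to baseline", {
  fs <- 50
  # two breaths; the first's volume stays 200 mL above its trigger baseline
  flow <- c(rep(26.4, 50), rep(-10, 50), rep(26.4, 50), rep(-30, 150))
  vol <- c(
    cumsum(rep(440 / 50, 50)), 440 - cumsum(rep(240 / 50, 50)),
    cumsum(rep(440 / 50, 50)), pmax(440 - cumsum(rep(440 / 150, 150)) * 1.5, 0)
  )
  s <- vent_stream(rep(5, 300), flow, vol, sample_rate_hz = fs)
  b <- segment_breaths(s)
  ev <- detect_double_trigger(s, b)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$volume_at_end_ml, 20)
})

test_that("injected double-trigger pairs are recovered exactly", {
  sim <- simulate_ventilation(
    sim_config(duration_s = 800, dt_rate = 0.06, seed = 31)
  )
  b <- segment_breaths(sim$stream)
  ev <- detect_double_trigger(sim$stream, b)
  truth <- sim$breath_log[sim$breath_log$type == "dt_first", ]
  expect_gt(nrow(truth), 0)
  expect_equal(nrow(ev), nrow(truth))
  expect_equal(ev$sample_index, truth$cycle_index)
})

test_that("flow deflections are detected with faithful features", {
  sim <- simulate_ventilation(
    sim_config(duration_s = 400, it_rate = 0.3, seed = 17)
  )
  b <- segment_breaths(sim$stream)
  ev <- detect_ineffective_trigger(sim$stream, b)
  gold <- sim$gold_events
  expect_equal(nrow(ev), nrow(gold))
  expect_true(all(abs(ev$sample_index - gold$sample_index) <= 2))
  expect_true(all(abs(ev$deflection_amplitude_lpm - 8) / 8 <= 0.1))
  expect_true(all(abs(ev$deflection_duration_s - 0.3) <= 0.06))
})

test_that("sub-threshold deflections are ignored", {
  for (args in list(
    list(it_amplitude_lpm = 4), # amplitude 4 <= 5 L/min
    list(it_duration_s = 0.10) # span 0.10 <= 0.12 s
  )) {
    cfg <- do.call(sim_config, c(
      list(duration_s = 200, it_rate = 0.4, seed = 23), args
    ))
    sim <- simulate_ventilation(cfg)
    expect_gt(nrow(sim$gold_events), 0)
    b <- segment_breaths(sim$stream)
    expect_equal(nrow(detect_ineffective_trigger(sim$stream, b)), 0)
  }
})

test_that("monotone expiratory decay produces no deflection events", {
  sim <- simulate_ventilation(sim_config(duration_s = 120, seed = 2))
  b <- segment_breaths(sim$stream)
  expect_equal(nrow(detect_ineffective_trigger(sim$stream, b)), 0)
})

test_that("detect_all merges both detectors deterministically", {
  sim0 <- simulate_ventilation(sim_config(duration_s = 120, seed = 4))
  expect_equal(nrow(detect_all(sim0$stream)), 0)

  sim <- simulate_ventilation(
    sim_config(duration_s = 400, dt_rate = 0.05, it_rate = 0.1, seed = 41)
  )
  ev <- detect_all(sim$stream)
  expect_equal(
    as.data.frame(table(ev$event_type)),
    as.data.frame(table(sim$gold_events$event_type))
  )
  expect_false(is.unsorted(ev$sample_index))
  expect_identical(detect_all(sim$stream), ev)
})

test_that("event features always satisfy the threshold inequalities", {
  cfg <- detector_config()
  sim <- simulate_ventilation(
    sim_config(
      duration_s = 400, dt_rate = 0.08, it_rate = 0.2,
      noise_sd_lpm = 1, seed = 19
    )
  )
  b <- segment_breaths(sim$stream)
  it <- detect_ineffective_trigger(sim$stream, b, cfg)
  expect_true(all(it$deflection_amplitude_lpm > cfg$it_amplitude_threshold))
  expect_true(all(it$deflection_duration_s > cfg$it_duration_threshold))
  dt <- detect_double_trigger(sim$stream, b, cfg)
  expect_true(all(
    dt$te_s < cfg$dt_te_ratio * dt$mean_ti_s |
      dt$volume_at_end_ml > cfg$volume_baseline_tol
  ))
})

test_that("deflection detection is invariant to a constant flow offset", {
  sim <- simulate_ventilation(sim_config(duration_s = 200, it_rate = 0.3, seed = 29))
  b <- segment_breaths(sim$stream)
  shifted <- vent_stream(
    sim$stream$paw, sim$stream$flow + 1.5, sim$stream$volume,
    sample_rate_hz = sample_rate(sim$stream)
  )
  a <- detect_ineffective_trigger(sim$stream, b)
  b2 <- detect_ineffective_trigger(shifted, b)
  expect_equal(b2$sample_index, a$sample_index)
  expect_equal(b2$deflection_amplitude_lpm, a$deflection_amplitude_lpm)
})

test_that("detector thresholds act monotonically", {
  sim <- simulate_ventilation(
    sim_config(
      duration_s = 400, dt_rate = 0.08, it_rate = 0.25,
      noise_sd_lpm = 1, seed = 37
    )
  )
  b <- segment_breaths(sim$stream)
  n_it <- vapply(c(3, 5, 7, 9), function(thr) {
    nrow(detect_ineffective_trigger(
      sim$stream, b, detector_config(it_amplitude_threshold = thr)
    ))
  }, numeric(1))
  expect_true(all(diff(n_it) <= 0))

  n_dt <- vapply(c(0.6, 0.5, 0.4, 0.3), function(r) {
    nrow(detect_double_trigger(
      sim$stream, b, detector_config(dt_te_ratio = r)
    ))
  }, numeric(1))
  expect_true(all(diff(n_dt) <= 0))
})
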