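test_that("the index is events over cycles plus ineffective triggers", {
  # 13 events among 95 cycles + 5 ineffective triggers: AI = 13%, severe
  expect_equal(asynchrony_index(13, 95, 5), 13)
  expect_equal(asynchrony_index(0, 60, 0), 0)
  expect_true(is.nan(asynchrony_index(0, 0, 0)))
})

make_window_fixture <- function(n_cycles = 95, n_it = 5, n_dt = 8, fs = 50,
                                window_s = 240) {
  # cycles spread over the window; IT events inside some breaths, DT on others
  trig <- round(seq(1, window_s * fs - 100, length.out = n_cycles))
  breaths <- tibble::tibble(
    breath = seq_len(n_cycles), trigger_index = trig,
    cycle_index = trig + 50L,
    end_index = c(trig[-1], window_s * fs),
    ti_s = 1, te_s = 2
  )
  events <- pva_events(
    event_type = c(
      rep("ineffective_trigger", n_it), rep("double_trigger", n_dt)
    ),
    sample_index = c(trig[seq_len(n_it)] + 80L, trig[n_it + seq_len(n_dt)] + 50L),
    source = "predicted"
  )
  list(breaths = breaths, events = events)
}

test_that("a 13-of-100 window computes 13% and alarms; an empty one does not", {
  fx <- make_window_fixture()
  ai <- compute_ai(fx$breaths, fx$events,
    stream_duration_s = 240,
    config = ai_config(window_s = 240)
  )
  expect_equal(nrow(ai), 1)
  expect_equal(ai$n_cycles, 95L)
  expect_equal(ai$n_ineffective, 5L)
  expect_equal(ai$denominator, 100L)
  expect_equal(ai$ai_pct, 13)
  expect_true(ai$alarm)

  quiet <- compute_ai(fx$breaths, pva_events(),
    stream_duration_s = 240,
    config = ai_config(window_s = 240)
  )
  expect_equal(quiet$ai_pct, 0)
  expect_false(quiet$alarm)
})

test_that("zero-denominator windows are NaN with the alarm off", {
  b <- tibble::tibble(
    breath = 1L, trigger_index = 1L, cycle_index = 51L, end_index = 150L,
    ti_s = 1, te_s = 2
  )
  ai <- suppressWarnings(compute_ai(
    b[0, ], pva_events(), 100,
    config = ai_config(window_s = 200, strict = FALSE)
  ))
  expect_true(all(is.nan(ai$ai_pct)))
  expect_false(any(ai$alarm))
})

test_that("the index is invariant to translating all sample indices", {
  fx <- make_window_fixture()
  shift <- 3000L
  b2 <- dplyr::mutate(fx$breaths,
    trigger_index = trigger_index + shift,
    cycle_index = cycle_index + shift, end_index = end_index + shift
  )
  e2 <- dplyr::mutate(fx$events, sample_index = sample_index + shift)
  a1 <- compute_ai(fx$breaths, fx$events, 240, config = ai_config(window_s = 240))
  a2 <- compute_ai(b2, e2, 240 + shift / 50,
    config = ai_config(window_s = 240)
  )
  expect_equal(a2$ai_pct[nrow(a2)], a1$ai_pct[1])
})

test_that("non-overlapping windows conserve the total event count", {
  sim <- simulate_ventilation(
    sim_config(duration_s = 600, it_rate = 0.2, dt_rate = 0.05, seed = 3)
  )
  b <- segment_breaths(sim$stream)
  ev <- detect_all(sim$stream)
  ai <- compute_ai(b, ev, stream_duration(sim$stream),
    config = ai_config(window_s = 200, step_s = 200, strict = FALSE)
  )
  expect_equal(sum(ai$n_events), nrow(ev))
  expect_equal(sum(ai$n_cycles), nrow(b))
  # sanity bound: numerator can exceed cycles only through double triggers
  expect_true(all(
    ai$n_events <= ai$denominator +
      sum(ev$event_type == "double_trigger")
  ))
})

test_that("steady-state AI tracks the programmed injection rate", {
  sim <- simulate_ventilation(
    sim_config(duration_s = 900, it_rate = 0.2, seed = 12)
  )
  b <- segment_breaths(sim$stream)
  ev <- detect_all(sim$stream)
  ai <- compute_ai(b, ev, stream_duration(sim$stream))
  # oracle: the same denominator rule applied to the injection bookkeeping
  n_it <- sum(sim$breath_log$type == "it_host")
  oracle_ai <- 100 * n_it / (nrow(sim$breath_log) + n_it)
  expect_lt(abs(mean(ai$ai_pct) - oracle_ai), 3)
})

test_that("alarm episodes merge consecutive alarmed windows", {
  fake <- tibble::tibble(
    window_end_s = 1:4, ai_pct = c(0, 15, 15, 0),
    alarm = c(FALSE, TRUE, TRUE, FALSE)
  )
  ep <- alarm_episodes(fake)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_s, 2)
  expect_equal(ep$end_s, 3)

  expect_equal(nrow(alarm_episodes(
    tibble::tibble(window_end_s = 1:2, ai_pct = 0, alarm = FALSE)
  )), 0)

  two <- alarm_episodes(tibble::tibble(
    window_end_s = 1:3, ai_pct = c(15, 0, 15),
    alarm = c(TRUE, FALSE, TRUE)
  ))
  expect_equal(nrow(two), 2)
})

test_that("window lengths outside 3-6 minutes need an explicit override", {
  expect_error(ai_config(window_s = 60), class = "ventasync_config_error")
  expect_silent(ai_config(window_s = 60, strict = FALSE))
  expect_error(ai_config(step_s = 0), class = "ventasync_config_error")
})
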