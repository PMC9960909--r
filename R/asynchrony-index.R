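# Sliding-window asynchrony index (AI) and severe-asynchrony alarming.
#
# AI over a window = 100 * (asynchrony events) / (ventilator cycles +
# ineffective-trigger count). Ineffective efforts are failed breaths the
# cycle count misses, so they are added to the denominator; double triggers
# are machine cycles already counted and add nothing extra. AI >= 10%
# defines severe asynchrony.

#' Asynchrony-index configuration
#'
#' @param window_s Sliding-window length in seconds. Default 240 (4 min);
#'   values outside the conventional 180-360 s band are rejected unless
#'   `strict = FALSE`.
#' @param step_s Window step in seconds. Default 1.
#' @param severe_threshold_pct Severe-asynchrony threshold on AI (percent);
#'   the alarm fires when AI >= this value. Default 10.
#' @param strict Enforce the 180-360 s window band (default `TRUE`).
#'
#' @return A list of class `ai_config`.
#' @export
ai_config <- function(window_s = 240, step_s = 1, severe_threshold_pct = 10,
                      strict = TRUE) {
  if (step_s <= 0) abort_config("step_s must be positive")
  if (window_s <= 0) abort_config("window_s must be positive")
  if (strict && (window_s < 180 || window_s > 360)) {
    abort_config("window_s outside 180-360 s; pass strict = FALSE to override")
  }
  structure(
    list(
      window_s = window_s, step_s = step_s,
      severe_threshold_pct = severe_threshold_pct
    ),
    class = "ai_config"
  )
}

#' Compute the sliding-window asynchrony index
#'
#' Slides a `window_s`-second window across the recording in `step_s` steps.
#' For each window `[t - window_s, t)`:
#'
#' * denominator = breaths whose trigger time falls in the window, plus
#'   ineffective-trigger events in the window;
#' * numerator = all asynchrony events in the window;
#' * `ai_pct = 100 * numerator / denominator` (NaN when the denominator is 0,
#'   with the alarm off);
#' * `alarm = ai_pct >= severe_threshold_pct`.
#'
#' Windows are half-open on the right so that with `step_s == window_s`
#' (non-overlapping windows) every event is counted exactly once.
#'
#' @param breaths Breath tibble from [segment_breaths()].
#' @param events Event tibble (detected or gold) indexed against the same
#'   stream.
#' @param stream_duration_s Recording length in seconds.
#' @param sample_rate_hz Sample rate used to convert event/breath indices to
#'   times. Default 50.
#' @param config An [ai_config()].
#'
#' @return An `ai_series` tibble with columns `window_start_s`,
#'   `window_end_s`, `n_events`, `n_cycles`, `n_ineffective`, `denominator`,
#'   `ai_pct`, `alarm`.
#' @export
#' @examples
#' sim <- simulate_ventilation(sim_config(duration_s = 300, it_rate = 0.25, seed = 2))
#' b <- segment_breaths(sim$stream)
#' ai <- compute_ai(b, detect_all(sim$stream), stream_duration(sim$stream))
#' summary(ai$ai_pct)
compute_ai <- function(breaths, events, stream_duration_s,
                       sample_rate_hz = 50, config = ai_config()) {
  if (stream_duration_s <= 0) abort_data("stream_duration_s must be positive")
  w <- config$window_s
  if (w > stream_duration_s) {
    warn("window longer than stream; computing a single truncated window")
    ends <- stream_duration_s
    starts <- 0
  } else {
    ends <- seq(w, stream_duration_s, by = config$step_s)
    starts <- ends - w
  }
  trig_t <- (breaths$trigger_index - 1) / sample_rate_hz
  ev_t <- (events$sample_index - 1) / sample_rate_hz
  it_t <- ev_t[events$event_type == "ineffective_trigger"]

  count_in <- function(x, lo, hi) {
    # half-open [lo, hi)
    vapply(
      seq_along(lo),
      function(i) sum(x >= lo[i] & x < hi[i]),
      integer(1)
    )
  }
  n_cycles <- count_in(trig_t, starts, ends)
  n_it <- count_in(it_t, starts, ends)
  n_ev <- count_in(ev_t, starts, ends)
  denom <- n_cycles + n_it
  ai <- ifelse(denom > 0, 100 * n_ev / denom, NaN)
  alarm <- !is.nan(ai) & ai >= config$severe_threshold_pct

  out <- tibble(
    window_start_s = starts, window_end_s = ends,
    n_events = n_ev, n_cycles = n_cycles, n_ineffective = n_it,
    denominator = denom, ai_pct = ai, alarm = alarm
  )
  structure(out,
    ai_config = config,
    class = c("ai_series", class(tibble()))
  )
}

#' Asynchrony index of one constructed window
#'
#' The windowless form of the index, useful for spot checks and reports:
#' `100 * n_events / (n_cycles + n_ineffective)`.
#'
#' @param n_events Number of asynchrony events in the window.
#' @param n_cycles Number of ventilator cycles in the window.
#' @param n_ineffective Number of ineffective-trigger events in the window.
#' @return AI in percent (NaN when the denominator is 0).
#' @export
#' @examples
#' asynchrony_index(13, 95, 5) # 13
asynchrony_index <- function(n_events, n_cycles, n_ineffective = 0) {
  denom <- n_cycles + n_ineffective
  ifelse(denom > 0, 100 * n_events / denom, NaN)
}

#' Merge alarmed windows into alarm episodes
#'
#' Maximal runs of consecutive `alarm = TRUE` windows are merged into
#' episodes reported by their window-end times.
#'
#' @param ai An `ai_series` from [compute_ai()].
#' @return A tibble with columns `start_s`, `end_s`, `n_windows`,
#'   `peak_ai_pct`; zero rows when nothing alarmed.
#' @export
alarm_episodes <- function(ai) {
  if (!"alarm" %in% names(ai)) abort_contract("not an ai_series")
  if (nrow(ai) == 0 || !any(ai$alarm)) {
    return(tibble(
      start_s = double(), end_s = double(),
      n_windows = integer(), peak_ai_pct = double()
    ))
  }
  r <- rle(ai$alarm)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- which(r$values)
  purrr::map_dfr(keep, function(k) {
    idx <- lo[k]:hi[k]
    tibble(
      start_s = ai$window_end_s[lo[k]],
      end_s = ai$window_end_s[hi[k]],
      n_windows = length(idx),
      peak_ai_pct = max(ai$ai_pct[idx])
    )
  })
}
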