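# Rule-based detectors for the two most common patient-ventilator
# asynchronies visible on the ventilator screen:
#
#   * double triggering  — two machine insufflations for one patient effort;
#     recognised when a breath has essentially no expiration (volume never
#     returns to baseline) or an expiratory time under half the rolling mean
#     inspiratory time;
#   * ineffective triggering — a patient effort during expiration that fails
#     to trigger the ventilator; recognised as a "flow deflection": the
#     expiratory flow curve transiently rises then falls, found via sign
#     changes of the first derivative of the smoothed flow.

#' Detector configuration
#'
#' @param it_amplitude_threshold Minimum flow-deflection amplitude in L/min
#'   for an ineffective-trigger call; strictly greater-than. Default 5.
#' @param it_duration_threshold Minimum deflection duration in seconds;
#'   strictly greater-than. Default 0.12.
#' @param it_duration_mode How deflection duration is measured:
#'   `"min_to_min"` (default; span between the bracketing flow minima) or
#'   `"max_to_min"` (peak to following minimum).
#' @param dt_te_ratio A breath pair is double-triggered when the first
#'   breath's expiratory time is strictly below `dt_te_ratio` times the mean
#'   inspiratory time. Default 0.5.
#' @param volume_baseline_tol Volume (mL) above the trigger baseline at breath
#'   end beyond which the expiration is deemed absent ("volume did not return
#'   to baseline"). Default 20.
#' @param derivative_smoothing_window Odd moving-average window (samples)
#'   applied to flow before differentiating; raw 50 Hz differences are
#'   noise-dominated. Default 5.
#'
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(it_amplitude_threshold = 5,
                            it_duration_threshold = 0.12,
                            it_duration_mode = c("min_to_min", "max_to_min"),
                            dt_te_ratio = 0.5,
                            volume_baseline_tol = 20,
                            derivative_smoothing_window = 5) {
  it_duration_mode <- arg_match(it_duration_mode)
  if (it_amplitude_threshold <= 0 || it_duration_threshold <= 0 ||
    volume_baseline_tol <= 0) {
    abort_config("detector thresholds must be positive")
  }
  if (dt_te_ratio <= 0 || dt_te_ratio >= 1) {
    abort_config("dt_te_ratio must lie in (0, 1)")
  }
  if (derivative_smoothing_window %% 2 != 1) {
    abort_config("derivative_smoothing_window must be odd")
  }
  structure(
    list(
      it_amplitude_threshold = it_amplitude_threshold,
      it_duration_threshold = it_duration_threshold,
      it_duration_mode = it_duration_mode,
      dt_te_ratio = dt_te_ratio,
      volume_baseline_tol = volume_baseline_tol,
      derivative_smoothing_window = derivative_smoothing_window
    ),
    class = "detector_config"
  )
}

#' Detect double triggering
#'
#' Examines each consecutive breath pair (i, i+1). The pair is flagged as one
#' double-trigger event — anchored at breath i's cycle point — when either
#'
#' * breath i has no effective expiration: `te_s == 0`, or its volume at
#'   breath end remains more than `volume_baseline_tol` mL above the volume at
#'   its trigger (the volume-time curve does not fall back to baseline); or
#' * breath i's expiratory time is strictly less than `dt_te_ratio` times the
#'   rolling mean inspiratory time over breaths up to and including i.
#'
#' @param s A [vent_stream()].
#' @param breaths Breath tibble from [segment_breaths()] on `s`.
#' @param config A [detector_config()].
#' @param ti_window Rolling window (breaths) for the mean inspiratory time;
#'   defaults to the segmentation default of 10.
#'
#' @return Event tibble (one row per flagged pair) with columns `event_type`,
#'   `breath_ordinal` (= i), `sample_index` (breath i's cycle index),
#'   `end_index`, `source`, and features `te_s`, `mean_ti_s`,
#'   `volume_at_end_ml`.
#' @export
detect_double_trigger <- function(s, breaths, config = detector_config(),
                                  ti_window = 10) {
  validate_stream_shape(s)
  if (nrow(breaths) < 2) {
    return(empty_pva_events("double_trigger"))
  }
  if (max(breaths$end_index) > nrow(s) + 1L) {
    abort_contract("breaths do not belong to this stream")
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(breaths) - 1L)) {
    b <- breaths[i, ]
    v_base <- s$volume[b$trigger_index]
    v_end <- s$volume[b$end_index - 1L]
    mean_ti <- mean_inspiratory_time(breaths, upto = i, window = ti_window)
    no_expiration <- b$te_s == 0 ||
      (v_end - v_base) > config$volume_baseline_tol
    short_te <- b$te_s < config$dt_te_ratio * mean_ti
    if (no_expiration || short_te) {
      k <- k + 1L
      rows[[k]] <- tibble(
        event_type = "double_trigger",
        breath_ordinal = b$breath,
        sample_index = b$cycle_index,
        end_index = breaths$cycle_index[i + 1L],
        source = "predicted",
        te_s = b$te_s,
        mean_ti_s = mean_ti,
        volume_at_end_ml = v_end - v_base
      )
    }
  }
  if (k == 0L) {
    return(empty_pva_events("double_trigger"))
  }
  arrange(bind_rows(rows), .data$sample_index)
}

#' Detect ineffective triggering
#'
#' Searches each breath's expiratory segment for "flow deflections": the flow
#' curve transiently rising then falling back. The segment's flow is smoothed
#' with a `derivative_smoothing_window`-sample moving average; local extrema
#' are located via sign changes of the first difference; each local maximum p
#' bracketed by local minima (m1, p, m2) forms a candidate deflection with
#'
#' * amplitude = flow(p) - max(flow(m1), flow(m2))  (L/min, conservative:
#'   referenced to the higher bracketing minimum), and
#' * duration = t(m2) - t(m1)  (min-to-min; or t(m2) - t(p) under
#'   `it_duration_mode = "max_to_min"`).
#'
#' An ineffective-trigger event anchored at p is emitted when amplitude
#' strictly exceeds `it_amplitude_threshold` and duration strictly exceeds
#' `it_duration_threshold`. Deflections do not overlap (consecutive maxima
#' share at most a bracketing minimum); one event per deflection.
#'
#' @inheritParams detect_double_trigger
#' @return Event tibble with columns `event_type`, `breath_ordinal`,
#'   `sample_index` (the deflection peak), `end_index` (= m2), `source`, and
#'   features `deflection_amplitude_lpm`, `deflection_duration_s`.
#' @export
detect_ineffective_trigger <- function(s, breaths, config = detector_config()) {
  validate_stream_shape(s)
  if (nrow(breaths) == 0) {
    return(empty_pva_events("ineffective_trigger"))
  }
  if (max(breaths$end_index) > nrow(s) + 1L) {
    abort_contract("breaths do not belong to this stream")
  }
  fs <- sample_rate(s)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(breaths))) {
    b <- breaths[i, ]
    if (b$end_index - b$cycle_index < 3) next
    seg <- s$flow[b$cycle_index:(b$end_index - 1L)]
    defl <- find_flow_deflections(seg, fs, config)
    if (nrow(defl) == 0) next
    k <- k + 1L
    rows[[k]] <- tibble(
      event_type = "ineffective_trigger",
      breath_ordinal = b$breath,
      sample_index = b$cycle_index + defl$peak - 1L,
      end_index = b$cycle_index + defl$m2 - 1L,
      source = "predicted",
      deflection_amplitude_lpm = defl$amplitude,
      deflection_duration_s = defl$duration
    )
  }
  if (k == 0L) {
    return(empty_pva_events("ineffective_trigger"))
  }
  arrange(bind_rows(rows), .data$sample_index)
}

# Move an extremum located on the smoothed curve to the raw curve's
# extremum within +/- h samples (clamped to [lo, hi] and the segment).
refine_extremum <- function(seg, at, h, which_fun, lo = 1L, hi = length(seg)) {
  lo <- max(lo, at - h, 1L)
  hi <- min(hi, at + h, length(seg))
  if (lo > hi) {
    return(at)
  }
  window <- lo:hi
  window[which(seg[window] == which_fun(seg[window]))[1]]
}

# Locate rise-then-fall deflections in one expiratory flow segment.
# Returns a tibble(peak, m1, m2, amplitude, duration) with indices relative
# to the segment (1-based).
find_flow_deflections <- function(seg, fs, config) {
  sm <- moving_average(seg, config$derivative_smoothing_window)
  d <- diff(sm)
  sgn <- sign(d)
  nz <- sgn != 0
  # carry the last nonzero sign through flat runs so plateaus don't spawn
  # spurious extrema
  sgn_f <- sgn
  last <- 0
  for (j in seq_along(sgn_f)) {
    if (nz[j]) last <- sgn_f[j] else sgn_f[j] <- last
  }
  flips <- which(sgn_f[-1] != sgn_f[-length(sgn_f)] & sgn_f[-1] != 0 &
    sgn_f[-length(sgn_f)] != 0) + 1L
  if (length(flips) == 0) {
    return(tibble(
      peak = integer(), m1 = integer(), m2 = integer(),
      amplitude = double(), duration = double()
    ))
  }
  kind <- ifelse(sgn_f[flips] < 0, "max", "min") # sign after the flip
  pos <- flips # extremum sits at the sample where the new slope begins
  rows <- list()
  k <- 0L
  maxima <- which(kind == "max")
  for (mi in maxima) {
    prev_mins <- which(kind == "min" & seq_along(kind) < mi)
    next_mins <- which(kind == "min" & seq_along(kind) > mi)
    if (length(prev_mins) == 0 || length(next_mins) == 0) next
    m1 <- pos[max(prev_mins)]
    m2 <- pos[min(next_mins)]
    p <- pos[mi]
    # smoothing only locates the extrema; positions are refined on the raw
    # curve within half a smoothing window, and the amplitude is read off the
    # raw flow, so neither feature is biased by the moving average
    h <- (config$derivative_smoothing_window - 1) / 2
    p <- refine_extremum(seg, p, h, max)
    m1 <- refine_extremum(seg, m1, h, min, hi = p - 1L)
    m2 <- refine_extremum(seg, m2, h, min, lo = p + 1L)
    amplitude <- seg[p] - max(seg[m1], seg[m2])
    duration <- switch(config$it_duration_mode,
      min_to_min = (m2 - m1) / fs,
      max_to_min = (m2 - p) / fs
    )
    if (amplitude > config$it_amplitude_threshold &&
      duration > config$it_duration_threshold) {
      k <- k + 1L
      rows[[k]] <- tibble(
        peak = p, m1 = m1, m2 = m2,
        amplitude = amplitude, duration = duration
      )
    }
  }
  if (k == 0L) {
    return(tibble(
      peak = integer(), m1 = integer(), m2 = integer(),
      amplitude = double(), duration = double()
    ))
  }
  bind_rows(rows)
}

#' Run both asynchrony detectors
#'
#' Segments the stream (unless breaths are supplied) and returns the union of
#' [detect_double_trigger()] and [detect_ineffective_trigger()] events sorted
#' by `sample_index`. Deterministic for fixed input and configuration.
#'
#' @param s A [vent_stream()].
#' @param seg_config A [seg_config()].
#' @param detector_config A [detector_config()].
#' @param breaths Optional pre-computed breath tibble.
#'
#' @return Event tibble (both types, feature columns filled per type,
#'   `NA` elsewhere).
#' @export
#' @examples
#' sim <- simulate_ventilation(sim_config(duration_s = 60, it_rate = 0.2, seed = 7))
#' detect_all(sim$stream)
detect_all <- function(s, seg_config = ventasync::seg_config(),
                       detector_config = ventasync::detector_config(),
                       breaths = NULL) {
  if (is.null(breaths)) breaths <- segment_breaths(s, seg_config)
  dt <- detect_double_trigger(s, breaths, detector_config,
    ti_window = seg_config$ti_avg_window
  )
  it <- detect_ineffective_trigger(s, breaths, detector_config)
  out <- bind_rows(dt, it)
  arrange(out, .data$sample_index)
}

empty_pva_events <- function(type) {
  base <- tibble(
    event_type = character(), breath_ordinal = integer(),
    sample_index = integer(), end_index = integer(), source = character()
  )
  if (type == "double_trigger") {
    base$te_s <- double()
    base$mean_ti_s <- double()
    base$volume_at_end_ml <- double()
  } else {
    base$deflection_amplitude_lpm <- double()
    base$deflection_duration_s <- double()
  }
  base
}
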