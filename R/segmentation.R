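# Breath segmentation by flow-threshold crossing with hysteresis.
#
# Ventilator breaths are delimited on the flow channel: inspiration starts
# where flow crosses above +flow_trigger_threshold (the machine is pushing gas
# in), expiration starts at the first later crossing below
# flow_cycle_threshold. Indices are 1-based; breaths are half-open
# [trigger_index, end_index) with end_index the next breath's trigger (or one
# past the stream end for the last breath).

#' Segmentation configuration
#'
#' @param flow_trigger_threshold Flow level (L/min) whose upward crossing
#'   marks inspiration onset. Default 2.
#' @param flow_cycle_threshold Flow level (L/min) whose downward crossing
#'   marks the inspiration-to-expiration transition. Default -2.
#' @param min_ti_s Minimum inspiratory time in seconds; shorter candidates are
#'   discarded as noise. Default 0.1.
#' @param min_breath_s Minimum total breath duration in seconds. Default 0.3.
#' @param ti_avg_window Number of breaths in the rolling mean used for the
#'   average inspiratory time (see [mean_inspiratory_time()]). Default 10.
#'
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(flow_trigger_threshold = 2, flow_cycle_threshold = -2,
                       min_ti_s = 0.1, min_breath_s = 0.3, ti_avg_window = 10) {
  if (!is.finite(flow_trigger_threshold) || !is.finite(flow_cycle_threshold)) {
    abort_config("flow thresholds must be finite")
  }
  if (min_ti_s >= min_breath_s) {
    abort_config("min_ti_s must be smaller than min_breath_s")
  }
  if (ti_avg_window < 1) abort_config("ti_avg_window must be >= 1")
  structure(
    list(
      flow_trigger_threshold = flow_trigger_threshold,
      flow_cycle_threshold = flow_cycle_threshold,
      min_ti_s = min_ti_s, min_breath_s = min_breath_s,
      ti_avg_window = ti_avg_window
    ),
    class = "seg_config"
  )
}

#' Segment a waveform stream into breaths
#'
#' Scans the flow channel for upward crossings of
#' `flow_trigger_threshold` (inspiration onset, armed only once flow has been
#' back below the threshold since the previous cycle) and, within each breath,
#' the first downward crossing of `flow_cycle_threshold` (expiration onset).
#' Candidates with inspiratory time below `min_ti_s` or total duration below
#' `min_breath_s` are discarded as noise.
#'
#' @param s A cleaned [vent_stream()].
#' @param config A [seg_config()].
#'
#' @return A tibble of breaths with columns `breath` (ordinal),
#'   `trigger_index`, `cycle_index`, `end_index` (1-based; `end_index`
#'   exclusive), `ti_s`, `te_s`.
#' @export
#' @examples
#' sim <- simulate_ventilation(sim_config(duration_s = 20, seed = 1))
#' segment_breaths(sim$stream)
segment_breaths <- function(s, config = seg_config()) {
  validate_stream_shape(s)
  fs <- sample_rate(s)
  if (nrow(s) < config$min_breath_s * fs) {
    abort_data("stream shorter than one minimal breath")
  }
  flow <- s$flow
  n <- length(flow)
  up <- config$flow_trigger_threshold
  down <- config$flow_cycle_threshold

  # upward crossings, armed: flow must have been <= threshold on the previous
  # sample; the state before the stream is taken as below threshold, so a
  # recording that opens mid-insufflation yields a breath at sample 1
  above <- flow > up
  triggers <- which(above & !c(FALSE, above[-n]))

  if (length(triggers) == 0) {
    return(empty_breaths())
  }

  rows <- list()
  k <- 0L
  n_trig <- length(triggers)
  for (i in seq_len(n_trig)) {
    tr <- triggers[i]
    end <- if (i < n_trig) triggers[i + 1] else n + 1L
    seg <- flow[tr:(end - 1L)]
    cyc_rel <- which(seg < down)
    if (length(cyc_rel) == 0) next # no expiratory crossing: incomplete breath
    cyc <- tr + cyc_rel[1] - 1L
    ti <- (cyc - tr) / fs
    dur <- (end - tr) / fs
    if (ti < config$min_ti_s || dur < config$min_breath_s) next
    k <- k + 1L
    rows[[k]] <- tibble(
      trigger_index = tr, cycle_index = cyc, end_index = end,
      ti_s = ti, te_s = (end - cyc) / fs
    )
  }
  if (k == 0L) {
    return(empty_breaths())
  }
  out <- bind_rows(rows)
  out <- mutate(out, breath = row_number())
  out[, c("breath", "trigger_index", "cycle_index", "end_index", "ti_s", "te_s")]
}

empty_breaths <- function() {
  tibble(
    breath = integer(), trigger_index = integer(), cycle_index = integer(),
    end_index = integer(), ti_s = double(), te_s = double()
  )
}

#' Rolling mean inspiratory time
#'
#' Arithmetic mean of `ti_s` over the last `min(window, upto)` breaths ending
#' at breath `upto` — the "average inspiratory time" against which the
#' double-trigger expiratory-time rule compares.
#'
#' @param breaths Breath tibble from [segment_breaths()].
#' @param upto 1-based ordinal of the last breath included.
#' @param window Rolling window length in breaths (default 10).
#' @return Mean inspiratory time in seconds.
#' @export
#' @examples
#' b <- tibble::tibble(ti_s = c(2, 1, 1, 1))
#' mean_inspiratory_time(b, upto = 4, window = 2) # 1
mean_inspiratory_time <- function(breaths, upto, window = 10) {
  if (nrow(breaths) == 0) abort_data("no breaths")
  if (upto < 1 || upto > nrow(breaths)) abort_contract("upto out of range")
  if (window < 1) abort_contract("window must be >= 1")
  idx <- max(1L, upto - window + 1L):upto
  mean(breaths$ti_s[idx])
}

#' Per-breath ventilation parameters
#'
#' Computes the parameters a ventilator report quotes per breath and per
#' stream: peak airway pressure, PEEP (mean `paw` over the last 0.2 s of
#' expiration, a stable end-expiratory plateau), tidal volume (maximum volume
#' minus volume at trigger), plus the stream-level respiratory rate
#' (breaths/min) and minute ventilation (mean tidal volume x rate, L/min).
#'
#' @param s A [vent_stream()].
#' @param breaths Breath tibble from [segment_breaths()] on the same stream.
#' @param peep_window_s Length of the end-expiratory window used for PEEP
#'   estimation (default 0.2 s).
#'
#' @return A tibble with one row per breath (`breath`, `peak_paw_cmh2o`,
#'   `peep_cmh2o`, `tidal_volume_ml`, `ti_s`, `te_s`) and attributes
#'   `resp_rate_per_min` and `minute_ventilation_l`.
#' @export
breath_parameters <- function(s, breaths, peep_window_s = 0.2) {
  validate_stream_shape(s)
  if (nrow(breaths) == 0) {
    out <- tibble(
      breath = integer(), peak_paw_cmh2o = double(), peep_cmh2o = double(),
      tidal_volume_ml = double(), ti_s = double(), te_s = double()
    )
    attr(out, "resp_rate_per_min") <- 0
    attr(out, "minute_ventilation_l") <- 0
    return(out)
  }
  if (max(breaths$end_index) > nrow(s) + 1L) {
    abort_contract("breaths do not belong to this stream")
  }
  fs <- sample_rate(s)
  npeep <- max(1L, round(peep_window_s * fs))
  per <- purrr::pmap(
    breaths[, c("breath", "trigger_index", "cycle_index", "end_index")],
    function(breath, trigger_index, cycle_index, end_index) {
      span <- trigger_index:(end_index - 1L)
      last <- max(cycle_index, end_index - npeep):(end_index - 1L)
      tibble(
        breath = breath,
        peak_paw_cmh2o = max(s$paw[span]),
        peep_cmh2o = mean(s$paw[last]),
        tidal_volume_ml = max(s$volume[span]) - s$volume[trigger_index]
      )
    }
  )
  out <- bind_rows(per)
  out$ti_s <- breaths$ti_s
  out$te_s <- breaths$te_s
  dur_min <- stream_duration(s) / 60
  rr <- nrow(breaths) / dur_min
  attr(out, "resp_rate_per_min") <- rr
  attr(out, "minute_ventilation_l") <- rr * mean(out$tidal_volume_ml) / 1000
  out
}
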