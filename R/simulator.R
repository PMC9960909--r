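# Synthetic ventilator waveform generator.
#
# Volume-control-style breaths from a single-compartment respiratory model:
# constant inspiratory flow delivers the set tidal volume over ti_s; airway
# pressure during insufflation follows the equation of motion
# Paw = R*Q + V/C + PEEP; expiration is passive exponential decay with time
# constant tau = R*C, integrated by forward Euler at the native sample rate.
# The volume channel is the running integral of machine flow, reset to zero
# at each trigger (as ventilator volume waveforms are displayed).
#
# Labelled asynchrony events are injected on demand:
#   * double trigger — the flagged breath's expiration is truncated to a
#     uniform draw in (0, 0.4*ti_s) and a second full insufflation follows
#     inside the same breath period, guaranteeing Te < 0.5 * mean Ti;
#   * ineffective trigger — a smooth deflection carved into the expiratory
#     flow decay (see inject_effort below): min-to-min span it_duration_s,
#     amplitude it_amplitude_lpm against the higher bracketing minimum, peak
#     kept below zero flow so the breath trigger never fires; a concurrent
#     1.5 cmH2O airway-pressure dip marks the effort. The effort moves no net
#     volume, so the volume channel follows passive mechanics.

#' Simulator configuration
#'
#' Defaults emulate an adult volume-control patient: tidal volume 440 mL,
#' PEEP 5 cmH2O, resistance 10 cmH2O/(L/s), compliance 50 mL/cmH2O
#' (expiratory time constant 0.5 s), 15 breaths/min with 1 s inspiration,
#' sampled at 50 Hz.
#'
#' @param duration_s Recording length in seconds (whole breath periods are
#'   generated; the count is `floor(duration_s * rr_per_min / 60)`).
#' @param sample_rate_hz Sample rate (default 50).
#' @param resistance Airway resistance, cmH2O/(L/s). Default 10.
#' @param compliance Respiratory-system compliance, mL/cmH2O. Default 50.
#' @param peep Positive end-expiratory pressure, cmH2O. Default 5.
#' @param tidal_volume_ml Set tidal volume, mL. Default 440.
#' @param ti_s Inspiratory time, seconds. Default 1.
#' @param rr_per_min Set respiratory rate, breaths/min. Default 15.
#' @param dt_rate Probability per breath slot of injecting a double-trigger
#'   pair. Default 0.
#' @param it_rate Probability per (non-DT) expiration of injecting an
#'   ineffective-trigger deflection. Default 0.
#' @param it_amplitude_lpm Deflection amplitude (peak above the higher
#'   bracketing flow minimum), L/min. Default 8.
#' @param it_duration_s Deflection min-to-min span, seconds. Default 0.3.
#' @param it_undershoot_lpm Depth the deflection dips below the decay curve
#'   at its bracketing minima, L/min. Default 2.
#' @param it_paw_dip_cmh2o Concurrent airway-pressure dip, cmH2O. Default 1.5.
#' @param noise_sd_lpm Gaussian noise SD added to the flow channel, L/min.
#'   Default 0.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60, sample_rate_hz = 50,
                       resistance = 10, compliance = 50, peep = 5,
                       tidal_volume_ml = 440, ti_s = 1, rr_per_min = 15,
                       dt_rate = 0, it_rate = 0,
                       it_amplitude_lpm = 8, it_duration_s = 0.3,
                       it_undershoot_lpm = 2, it_paw_dip_cmh2o = 1.5,
                       noise_sd_lpm = 0, seed = NULL) {
  phys <- c(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    resistance = resistance, compliance = compliance,
    tidal_volume_ml = tidal_volume_ml, ti_s = ti_s, rr_per_min = rr_per_min
  )
  if (any(!is.finite(phys)) || any(phys <= 0)) {
    abort_config("physical simulator parameters must be positive and finite")
  }
  if (dt_rate < 0 || dt_rate >= 1 || it_rate < 0 || it_rate >= 1) {
    abort_config("dt_rate and it_rate must lie in [0, 1)")
  }
  period_s <- 60 / rr_per_min
  tau_s <- resistance * compliance / 1000
  if (period_s - ti_s < 3 * tau_s) {
    abort_config("breath period leaves too little expiratory time (< 3 time constants)")
  }
  if (dt_rate > 0 && period_s < 2.4 * ti_s + 3 * tau_s) {
    abort_config("breath period too short to host a double-trigger pair")
  }
  te_s <- period_s - ti_s
  if (it_rate > 0 && it_duration_s * 5 / 3 > 0.6 * te_s) {
    abort_config("it_duration_s too long for the expiratory phase")
  }
  structure(
    list(
      duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      resistance = resistance, compliance = compliance, peep = peep,
      tidal_volume_ml = tidal_volume_ml, ti_s = ti_s,
      rr_per_min = rr_per_min, dt_rate = dt_rate, it_rate = it_rate,
      it_amplitude_lpm = it_amplitude_lpm, it_duration_s = it_duration_s,
      it_undershoot_lpm = it_undershoot_lpm,
      it_paw_dip_cmh2o = it_paw_dip_cmh2o,
      noise_sd_lpm = noise_sd_lpm, seed = seed,
      period_s = period_s, tau_s = tau_s
    ),
    class = "sim_config"
  )
}

#' One Euler step of the single-compartment equation of motion
#'
#' Advances the lung volume by `flow * dt` (L/min converted to mL/s via
#' 1000/60) and returns the airway pressure from
#' `Paw = R*Q + V/C + PEEP`.
#'
#' @param state List with element `volume_ml` (current volume above FRC, mL).
#' @param flow_lpm Flow during the step, L/min (positive into the patient).
#' @param config A [sim_config()].
#' @return List with updated `volume_ml` and the step's `paw_cmh2o`.
#' @export
#' @examples
#' s <- list(volume_ml = 0)
#' for (i in 1:50) s <- mechanics_step(s, 30, sim_config())
#' s$volume_ml # 500 mL after 1 s at 30 L/min
mechanics_step <- function(state, flow_lpm, config = sim_config()) {
  dt <- 1 / config$sample_rate_hz
  v <- state$volume_ml + flow_lpm * (1000 / 60) * dt
  paw <- config$peep + config$resistance * (flow_lpm / 60) +
    v / config$compliance
  list(volume_ml = v, paw_cmh2o = paw)
}

# half-cosine interpolation between two values (smooth, zero end slopes)
half_cosine <- function(from, to, n) {
  from + (to - from) * (1 - cos(pi * seq(0, 1, length.out = n))) / 2
}

# Carve an ineffective-effort deflection into one expiratory flow segment.
#
# The effort interrupts the early, steep part of the passive decay: flow dips
# `undershoot` below the curve (left minimum m1 — guaranteed local because
# the replacement descends while the decay was rising), climbs to a peak just
# below zero flow (so the +2 L/min breath trigger is never crossed), falls to
# a shallow right minimum m2, and rejoins the decay. By construction the
# min-to-min span is `duration_s` and the amplitude against the HIGHER
# bracketing minimum (m2) is `amplitude`, i.e. exactly the features the
# deflection detector measures.
#
# Returns list(flow, m1, peak, m2, start, end) with 1-based segment indices,
# or NULL when the deflection does not fit this expiration.
inject_effort <- function(flow_seg, fs, amplitude, duration_s, undershoot,
                          peak_target_lpm = -1) {
  n_d <- round(duration_s * fs) # min-to-min span, samples
  # edge descents: at least as wide as the detector's default smoothing
  # window, so the bracketing minima are resolvable after smoothing
  n_edge <- max(5L, round(n_d / 3))
  # right anchor: first sample where the decay has recovered to the level the
  # right minimum must sit on
  b3_target <- peak_target_lpm - amplitude + undershoot
  j3 <- which(flow_seg >= b3_target)[1]
  if (is.na(j3)) {
    return(NULL)
  }
  m2 <- j3 - n_edge
  m1 <- m2 - n_d
  j0 <- m1 - n_edge
  p <- m1 + round(n_d / 2)
  if (j0 < 2 || j3 > length(flow_seg) - 2) {
    return(NULL)
  }
  b0 <- flow_seg[j0]
  b3 <- flow_seg[j3]
  m1_val <- b0 - undershoot
  m2_val <- b3 - undershoot
  peak_val <- max(m1_val, m2_val) + amplitude
  flow_seg[j0:m1] <- half_cosine(b0, m1_val, m1 - j0 + 1)
  flow_seg[m1:p] <- half_cosine(m1_val, peak_val, p - m1 + 1)
  flow_seg[p:m2] <- half_cosine(peak_val, m2_val, m2 - p + 1)
  flow_seg[m2:j3] <- half_cosine(m2_val, b3, j3 - m2 + 1)
  list(flow = flow_seg, m1 = m1, peak = p, m2 = m2, start = j0, end = j3)
}

#' Simulate a labelled ventilator recording
#'
#' Generates a [vent_stream()] of volume-control breaths with optional
#' injected double-trigger and ineffective-trigger events, plus gold-standard
#' annotations and a per-breath truth log. Identical configuration (including
#' `seed`) gives bit-identical output.
#'
#' Random draws are consumed in a fixed order — per breath slot: one uniform
#' for the DT decision, then either one uniform for the expiration truncation
#' (DT slots) or one uniform for the IT decision (other slots); flow noise,
#' if any, is drawn last.
#'
#' @param config A [sim_config()].
#' @return A list of class `vent_sim` with elements `stream`
#'   (a [vent_stream()]), `gold_events` (annotation tibble, `source = "gold"`),
#'   `breath_log` (tibble: `ordinal`, `type`, `trigger_index`, `cycle_index`,
#'   `end_index`, `ti_s`, `te_s`) and `config`.
#' @export
#' @examples
#' sim <- simulate_ventilation(sim_config(duration_s = 60, seed = 1))
#' nrow(sim$breath_log) # 15 breaths at 15/min for 60 s
simulate_ventilation <- function(config = sim_config()) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) abort_config("config must be a sim_config")
  if (!is.null(cfg$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(cfg$seed)
  }
  fs <- cfg$sample_rate_hz
  dt <- 1 / fs
  n_period <- round(cfg$period_s * fs)
  n_ti <- round(cfg$ti_s * fs)
  n_slots <- floor(cfg$duration_s * cfg$rr_per_min / 60 + 1e-9)
  if (n_slots < 1) abort_config("duration_s shorter than one breath period")
  q_insp_lpm <- cfg$tidal_volume_ml / cfg$ti_s * 60 / 1000
  q_insp_mls <- cfg$tidal_volume_ml / cfg$ti_s
  tau <- cfg$tau_s

  # insufflation phase (shared by every breath): right-rectangle integral of
  # constant flow — the vectorised equivalent of iterating mechanics_step()
  v_insp <- cumsum(rep(q_insp_mls * dt, n_ti))
  paw_insp <- cfg$peep + cfg$resistance * (q_insp_lpm / 60) +
    v_insp / cfg$compliance
  flow_insp <- rep(q_insp_lpm, n_ti)

  # passive expiration for n samples from starting volume v0 (forward Euler)
  expire <- function(n, v0) {
    decay <- (1 - dt / tau)^(seq_len(n) - 1)
    v_pre <- v0 * decay # volume entering each step
    flow_mls <- -v_pre / tau
    list(
      flow = flow_mls * 60 / 1000,
      volume = v_pre * (1 - dt / tau),
      paw = rep(cfg$peep, n)
    )
  }

  flow <- vector("list", 2 * n_slots)
  paw <- vector("list", 2 * n_slots)
  volume <- vector("list", 2 * n_slots)
  nseg <- 0L
  push <- function(f, p, v) {
    nseg <<- nseg + 1L
    flow[[nseg]] <<- f
    paw[[nseg]] <<- p
    volume[[nseg]] <<- v
  }

  breath_rows <- list()
  gold_rows <- list()
  n_breaths <- 0L
  n_gold <- 0L
  pos <- 0L # samples emitted so far

  add_breath <- function(type, trig, cyc, end) {
    n_breaths <<- n_breaths + 1L
    breath_rows[[n_breaths]] <<- tibble(
      ordinal = n_breaths, type = type,
      trigger_index = trig, cycle_index = cyc, end_index = end,
      ti_s = (cyc - trig) / fs, te_s = (end - cyc) / fs
    )
  }

  for (slot in seq_len(n_slots)) {
    u_dt <- runif(1)
    is_dt <- u_dt < cfg$dt_rate
    if (is_dt) {
      n_tr <- max(1L, round(runif(1) * 0.4 * cfg$ti_s * fs))
      n_rem <- n_period - 2L * n_ti - n_tr
      trig1 <- pos + 1L
      cyc1 <- trig1 + n_ti
      trig2 <- cyc1 + n_tr
      cyc2 <- trig2 + n_ti
      end2 <- pos + n_period + 1L
      e1 <- expire(n_tr, cfg$tidal_volume_ml)
      e2 <- expire(n_rem, cfg$tidal_volume_ml)
      push(flow_insp, paw_insp, v_insp)
      push(e1$flow, e1$paw, e1$volume)
      push(flow_insp, paw_insp, v_insp)
      push(e2$flow, e2$paw, e2$volume)
      add_breath("dt_first", trig1, cyc1, trig2)
      add_breath("dt_second", trig2, cyc2, end2)
      n_gold <- n_gold + 1L
      gold_rows[[n_gold]] <- tibble(
        event_type = "double_trigger", sample_index = cyc1,
        end_index = trig2, source = "gold"
      )
    } else {
      u_it <- runif(1)
      is_it <- u_it < cfg$it_rate
      n_te <- n_period - n_ti
      trig <- pos + 1L
      cyc <- trig + n_ti
      end <- pos + n_period + 1L
      e <- expire(n_te, cfg$tidal_volume_ml)
      if (is_it) {
        eff <- inject_effort(
          e$flow, fs, cfg$it_amplitude_lpm, cfg$it_duration_s,
          cfg$it_undershoot_lpm
        )
        if (is.null(eff)) {
          abort_config(
            "ineffective-trigger deflection does not fit the expiratory phase"
          )
        }
        e$flow <- eff$flow
        span <- eff$start:eff$end
        u <- seq(0, 1, length.out = length(span))
        e$paw[span] <- e$paw[span] -
          cfg$it_paw_dip_cmh2o * (1 - cos(2 * pi * u)) / 2
        n_gold <- n_gold + 1L
        gold_rows[[n_gold]] <- tibble(
          event_type = "ineffective_trigger",
          sample_index = cyc + eff$peak - 1L,
          end_index = cyc + eff$end - 1L, source = "gold"
        )
      }
      push(flow_insp, paw_insp, v_insp)
      push(e$flow, e$paw, e$volume)
      add_breath(if (is_it) "it_host" else "normal", trig, cyc, end)
    }
    pos <- pos + n_period
  }

  flow <- unlist(flow[seq_len(nseg)])
  paw <- unlist(paw[seq_len(nseg)])
  volume <- unlist(volume[seq_len(nseg)])
  if (cfg$noise_sd_lpm > 0) {
    flow <- flow + rnorm(length(flow), 0, cfg$noise_sd_lpm)
  }

  stream <- vent_stream(paw, flow, volume,
    sample_rate_hz = fs,
    meta = list(source = "ventasync simulator", ventilation_mode = "VCV",
      peep_set_cmh2o = cfg$peep)
  )
  gold <- if (n_gold > 0) {
    arrange(bind_rows(gold_rows[seq_len(n_gold)]), .data$sample_index)
  } else {
    pva_events()
  }
  structure(
    list(
      stream = stream, gold_events = gold,
      breath_log = bind_rows(breath_rows[seq_len(n_breaths)]),
      config = cfg
    ),
    class = "vent_sim"
  )
}

#' @export
print.vent_sim <- function(x, ...) {
  cat(sprintf(
    "# Simulated ventilation: %d breaths, %.0f s at %g Hz; %d gold event(s)\n",
    nrow(x$breath_log), stream_duration(x$stream),
    sample_rate(x$stream), nrow(x$gold_events)
  ))
  invisible(x)
}
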