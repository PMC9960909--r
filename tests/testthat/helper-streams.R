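# Shared fixtures, built in code.

# Square-wave breath train: n breaths of ti_s inspiration at insp_lpm and
# te_s expiration at exp_lpm, 50 Hz. Volume is the within-breath running
# integral of flow unless zero_volume = TRUE.
square_stream <- function(n = 10, ti_s = 1, te_s = 2, insp_lpm = 26.4,
                          exp_lpm = -30, fs = 50, zero_volume = FALSE) {
  n_ti <- round(ti_s * fs)
  n_te <- round(te_s * fs)
  flow <- rep(c(rep(insp_lpm, n_ti), rep(exp_lpm, n_te)), n)
  vol <- if (zero_volume) {
    rep(0, length(flow))
  } else {
    unlist(replicate(n,
      cumsum(c(rep(insp_lpm, n_ti), rep(exp_lpm, n_te)) * 1000 / 60 / fs),
      simplify = FALSE
    ))
  }
  vent_stream(
    paw = rep(5, length(flow)), flow = flow, volume = vol,
    sample_rate_hz = fs
  )
}

# Breath train with per-breath expiratory durations (in seconds); used to
# construct double-trigger morphologies with exact Te. Volume is zero so the
# Te rule is exercised in isolation.
breaths_with_te <- function(te_s, ti_s = 1, insp_lpm = 26.4, exp_lpm = -30,
                            fs = 50) {
  n_ti <- round(ti_s * fs)
  flow <- unlist(lapply(te_s, function(te) {
    c(rep(insp_lpm, n_ti), rep(exp_lpm, round(te * fs)))
  }))
  vent_stream(
    paw = rep(5, length(flow)), flow = flow,
    volume = rep(0, length(flow)), sample_rate_hz = fs
  )
}
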