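# Structured analysis report for one asynchrony-index window: the machine
# counterpart of the bedside report a clinician receives when severe
# asynchrony is flagged — basic info, diagnostic reference (AI + severity),
# deterministic prompt text, ventilation parameters over the window, and the
# waveform excerpt bounds.

#' Generate an analysis report for one AI window
#'
#' @param stream A [vent_stream()].
#' @param breaths Breath tibble from [segment_breaths()].
#' @param events Event tibble from [detect_all()].
#' @param ai An `ai_series` from [compute_ai()].
#' @param window_end_s End time of the AI window to report on; must match a
#'   row of `ai` (nearest window within half a step is accepted).
#'
#' @return An object of class `pva_report`: a named list with elements
#'   `basic_info`, `diagnostic_reference`, `prompts_findings`,
#'   `ventilator_parameters`, `waveform_excerpt`. Serialise with
#'   [report_json()]; print for a human-readable view.
#' @export
#' @examples
#' sim <- simulate_ventilation(sim_config(duration_s = 300, it_rate = 0.25, seed = 4))
#' b <- segment_breaths(sim$stream)
#' ev <- detect_all(sim$stream)
#' ai <- compute_ai(b, ev, stream_duration(sim$stream))
#' rep <- generate_report(sim$stream, b, ev, ai, max(ai$window_end_s))
#' print(rep)
generate_report <- function(stream, breaths, events, ai, window_end_s) {
  cfg <- attr(ai, "ai_config")
  row <- which(abs(ai$window_end_s - window_end_s) < cfg$step_s / 2)
  if (length(row) == 0) {
    abort_contract(sprintf("no AI window ends at %.1f s", window_end_s))
  }
  row <- row[1]
  w <- ai[row, ]
  fs <- sample_rate(stream)
  lo_t <- w$window_start_s
  hi_t <- w$window_end_s
  lo_i <- as.integer(floor(lo_t * fs)) + 1L
  hi_i <- min(nrow(stream), as.integer(ceiling(hi_t * fs)))

  in_window <- function(idx) (idx - 1) / fs >= lo_t & (idx - 1) / fs < hi_t
  ev_w <- filter(events, in_window(.data$sample_index))
  counts <- list(
    double_trigger = sum(ev_w$event_type == "double_trigger"),
    ineffective_trigger = sum(ev_w$event_type == "ineffective_trigger")
  )
  b_w <- filter(breaths, in_window(.data$trigger_index))
  params <- if (nrow(b_w) > 0) {
    bp <- breath_parameters(stream, b_w)
    list(
      peak_pressure_cmh2o = max(bp$peak_paw_cmh2o),
      peep_cmh2o = round_half_up(mean(bp$peep_cmh2o), 2),
      total_resp_rate_per_min = round_half_up(nrow(b_w) / ((hi_t - lo_t) / 60), 2),
      tidal_volume_ml = round_half_up(mean(bp$tidal_volume_ml), 1),
      minute_ventilation_l = round_half_up(
        nrow(b_w) / ((hi_t - lo_t) / 60) * mean(bp$tidal_volume_ml) / 1000, 2
      )
    )
  } else {
    list(
      peak_pressure_cmh2o = NULL, peep_cmh2o = NULL,
      total_resp_rate_per_min = 0, tidal_volume_ml = NULL,
      minute_ventilation_l = 0
    )
  }
  meta <- stream_meta(stream)
  severe <- isTRUE(w$alarm)
  ai_val <- if (is.nan(w$ai_pct)) NULL else round_half_up(w$ai_pct, 2)

  n_ev <- counts$double_trigger + counts$ineffective_trigger
  prompts <- if (n_ev == 0) {
    "No patient-ventilator asynchrony detected in this window."
  } else {
    dominant <- if (counts$double_trigger >= counts$ineffective_trigger) {
      "double triggering"
    } else {
      "ineffective triggering"
    }
    c(
      sprintf(
        "%d asynchrony event(s) in the %.0f-s window; dominant type: %s.",
        n_ev, hi_t - lo_t, dominant
      ),
      if (severe) {
        sprintf(
          "Severe patient-ventilator asynchrony: index %.2f%% >= %.0f%%. Review ventilator settings.",
          w$ai_pct, cfg$severe_threshold_pct
        )
      } else {
        sprintf("Asynchrony index %.2f%% below the severe threshold.", w$ai_pct)
      }
    )
  }

  structure(
    list(
      basic_info = meta,
      diagnostic_reference = list(
        window_s = hi_t - lo_t,
        window_end_s = hi_t,
        ai_pct = ai_val,
        severe = severe,
        event_counts = counts
      ),
      prompts_findings = as.list(prompts),
      ventilator_parameters = params,
      waveform_excerpt = list(start_index = lo_i, end_index = hi_i)
    ),
    class = "pva_report"
  )
}

#' Serialise a report to JSON
#'
#' Byte-identical output for identical inputs; validates structurally against
#' the schema shipped at `system.file("schema", "pva-report.schema.json",
#' package = "ventasync")`.
#'
#' @param report A `pva_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  if (!inherits(report, "pva_report")) abort_contract("not a pva_report")
  js <- jsonlite::toJSON(unclass(report),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
format.pva_report <- function(x, ...) {
  dr <- x$diagnostic_reference
  vp <- x$ventilator_parameters
  fmt <- function(v, unit = "") if (is.null(v)) "-" else paste0(v, unit)
  c(
    "# Mechanical ventilation analysis report",
    "",
    "## Diagnostic reference",
    sprintf("- Asynchrony index: %s (window %.0f s ending %.0f s)",
      fmt(dr$ai_pct, "%"), dr$window_s, dr$window_end_s),
    sprintf("- Severe asynchrony: %s", if (dr$severe) "YES" else "no"),
    sprintf("- Double-trigger events: %d", dr$event_counts$double_trigger),
    sprintf("- Ineffective-trigger events: %d", dr$event_counts$ineffective_trigger),
    "",
    "## Prompts and findings",
    paste0("- ", unlist(x$prompts_findings)),
    "",
    "## Ventilator parameters (window)",
    sprintf("- Peak pressure: %s", fmt(vp$peak_pressure_cmh2o, " cmH2O")),
    sprintf("- PEEP: %s", fmt(vp$peep_cmh2o, " cmH2O")),
    sprintf("- Total respiratory rate: %s", fmt(vp$total_resp_rate_per_min, " /min")),
    sprintf("- Tidal volume: %s", fmt(vp$tidal_volume_ml, " mL")),
    sprintf("- Minute ventilation: %s", fmt(vp$minute_ventilation_l, " L/min")),
    "",
    sprintf(
      "Waveform excerpt: samples %d-%d", x$waveform_excerpt$start_index,
      x$waveform_excerpt$end_index
    )
  )
}

#' @export
print.pva_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
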