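# ggplot2 visualisations.

#' Plot a ventilator waveform stream
#'
#' Facets the pressure, flow and volume channels over time; detected or gold
#' events, if supplied, are marked on the flow panel.
#'
#' @param object A [vent_stream()].
#' @param events Optional event tibble to overlay.
#' @param window Optional numeric `c(start_s, end_s)` to restrict the time
#'   axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vent_stream <- function(object, events = NULL, window = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window)) {
    df <- filter(df, .data$time >= window[1], .data$time <= window[2])
  }
  long <- tidyr::pivot_longer(df, c("paw", "flow", "volume"),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel,
    levels = c("paw", "flow", "volume"),
    labels = c("Paw (cmH2O)", "Flow (L/min)", "Volume (mL)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL)
  if (!is.null(events) && nrow(events) > 0) {
    ev <- mutate(events,
      time = (.data$sample_index - 1) / sample_rate(object),
      channel = factor("Flow (L/min)", levels = levels(long$channel))
    )
    if (!is.null(window)) {
      ev <- filter(ev, .data$time >= window[1], .data$time <= window[2])
    }
    flow_at <- object$flow[ev$sample_index]
    ev$value <- flow_at
    p <- p + ggplot2::geom_point(
      data = ev,
      ggplot2::aes(colour = .data$event_type), shape = 17, size = 2
    ) +
      ggplot2::labs(colour = "Event")
  }
  p
}

#' Plot an asynchrony-index series
#'
#' AI (percent) against window end time, with the severe threshold as a
#' dashed line and alarmed windows shaded.
#'
#' @param object An `ai_series` from [compute_ai()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ai_series <- function(object, ...) {
  cfg <- attr(object, "ai_config")
  thr <- if (!is.null(cfg)) cfg$severe_threshold_pct else 10
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_end_s, y = .data$ai_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "Window end (s)", y = "Asynchrony index (%)",
      title = "Sliding-window asynchrony index"
    )
  ep <- alarm_episodes(object)
  if (nrow(ep) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ep,
      ggplot2::aes(
        xmin = .data$start_s, xmax = .data$end_s,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, alpha = 0.15, fill = "red"
    )
  }
  p
}

#' Convenience wrapper around [autoplot.vent_stream()]
#'
#' @inheritParams autoplot.vent_stream
#' @param s A [vent_stream()].
#' @return A ggplot object.
#' @export
plot_stream <- function(s, events = NULL, window = NULL) {
  autoplot(s, events = events, window = window)
}
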