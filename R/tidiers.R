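# broom-style tidiers.

#' Tidy a confusion matrix
#'
#' @param x A `pva_confusion`.
#' @param ... Unused.
#' @return A tibble with one row per cell (`cell`, `count`).
#' @export
tidy.pva_confusion <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"), count = c(x$tp, x$fp, x$fn, x$tn))
}

#' One-row summary of a confusion matrix
#'
#' @param x A `pva_confusion`.
#' @param ... Passed to [pva_metrics()].
#' @return A one-row tibble with the cell counts, total and the four
#'   diagnostic metrics.
#' @export
glance.pva_confusion <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
      n = x$tp + x$fp + x$fn + x$tn
    ),
    pva_metrics(x, ...)
  )
}

#' Tidy a detector evaluation
#'
#' @param x A `pva_evaluation` from [evaluate_run()].
#' @param ... Unused.
#' @return A tibble with one row per event type: counts and metrics.
#' @export
tidy.pva_evaluation <- function(x, ...) {
  purrr::map_dfr(names(x), function(tp) {
    dplyr::bind_cols(tibble(event_type = tp), glance(x[[tp]]$confusion))
  })
}

#' One-row summary of a detector evaluation
#'
#' @param x A `pva_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble: breaths evaluated and per-type sensitivity and
#'   specificity.
#' @export
glance.pva_evaluation <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_breaths = attr(x, "n_breaths"),
    dt_sensitivity_pct = td$sensitivity_pct[td$event_type == "double_trigger"],
    dt_specificity_pct = td$specificity_pct[td$event_type == "double_trigger"],
    it_sensitivity_pct = td$sensitivity_pct[td$event_type == "ineffective_trigger"],
    it_specificity_pct = td$specificity_pct[td$event_type == "ineffective_trigger"]
  )
}

#' Glance at an asynchrony-index series
#'
#' @param x An `ai_series` from [compute_ai()].
#' @param ... Unused.
#' @return A one-row tibble: number of windows, peak and mean AI, alarmed
#'   window count and episode count.
#' @export
glance.ai_series <- function(x, ...) {
  ok <- !is.nan(x$ai_pct)
  tibble(
    n_windows = nrow(x),
    peak_ai_pct = if (any(ok)) max(x$ai_pct[ok]) else NaN,
    mean_ai_pct = if (any(ok)) mean(x$ai_pct[ok]) else NaN,
    n_alarm_windows = sum(x$alarm),
    n_alarm_episodes = nrow(alarm_episodes(x))
  )
}
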