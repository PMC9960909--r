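# Detector evaluation against gold-standard annotations.
#
# The unit of analysis is the breath: events (gold or predicted) are
# projected onto the breath containing them, per-breath boolean labels are
# cross-tabulated into a 2x2 confusion matrix, and the four standard
# diagnostic metrics are derived (sensitivity, specificity, PPV, NPV).

#' Project events onto per-breath labels
#'
#' A breath is labelled positive for `event_type` iff at least one event of
#' that type is anchored within its `[trigger_index, end_index)` span. Events
#' falling outside every breath are attached to the nearest breath when
#' within `tolerance_s` seconds of one, otherwise dropped with a warning.
#'
#' @param breaths Breath tibble from [segment_breaths()].
#' @param events Event tibble.
#' @param event_type `"double_trigger"` or `"ineffective_trigger"`.
#' @param sample_rate_hz Sample rate for the straggler tolerance. Default 50.
#' @param tolerance_s Matching tolerance for events outside all breaths.
#'   Default 0.5 s.
#' @return Logical vector, one element per breath.
#' @export
label_breaths <- function(breaths, events, event_type, sample_rate_hz = 50,
                          tolerance_s = 0.5) {
  event_type <- arg_match(event_type, pva_event_types)
  labels <- rep(FALSE, nrow(breaths))
  if (nrow(breaths) == 0) {
    return(labels)
  }
  ev <- filter(events, .data$event_type == !!event_type)
  if (nrow(ev) == 0) {
    return(labels)
  }
  for (si in ev$sample_index) {
    hit <- which(breaths$trigger_index <= si & si < breaths$end_index)
    if (length(hit) >= 1) {
      labels[hit[1]] <- TRUE
    } else {
      # straggler: distance to the nearest breath edge, in samples
      d_lo <- breaths$trigger_index - si
      d_hi <- si - (breaths$end_index - 1L)
      dist <- pmax(pmax(d_lo, d_hi), 0L)
      nearest <- which.min(dist)
      if (dist[nearest] <= tolerance_s * sample_rate_hz) {
        warn(sprintf(
          "event at sample %d lies outside all breaths; attached to breath %d",
          si, breaths$breath[nearest]
        ))
        labels[nearest] <- TRUE
      } else {
        warn(sprintf(
          "event at sample %d lies > %.1f s from any breath; dropped",
          si, tolerance_s
        ))
      }
    }
  }
  labels
}

#' Build a 2x2 confusion matrix from per-breath labels
#'
#' @param pred Logical vector of predicted labels.
#' @param gold Logical vector of gold-standard labels (same length).
#' @return An object of class `pva_confusion`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion(pred = c(TRUE, FALSE), gold = c(TRUE, FALSE))
confusion <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    abort_contract("pred and gold must have equal length")
  }
  pred <- as.logical(pred)
  gold <- as.logical(gold)
  confusion_matrix(
    tp = sum(pred & gold), fp = sum(pred & !gold),
    fn = sum(!pred & gold), tn = sum(!pred & !gold)
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return An object of class `pva_confusion`.
#' @export
#' @examples
#' confusion_matrix(tp = 481, fp = 3, fn = 235, tn = 3777)
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort_contract("confusion-matrix cells must be non-negative integers")
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
    class = "pva_confusion"
  )
}

#' @export
print.pva_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn),
    nrow = 2,
    dimnames = list(pred = c("positive", "negative"), gold = c("positive", "negative"))
  )
  cat("# Confusion matrix (rows: predicted, cols: gold)\n")
  print(m)
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`,
#' PPV `100*tp/(tp+fp)` and NPV `100*tn/(tn+fn)`, on the percent scale,
#' rounded half-up to `decimals` places. Components with a zero denominator
#' are `NaN`.
#'
#' @param cm A `pva_confusion` from [confusion()] or [confusion_matrix()].
#' @param decimals Decimal places (half-up). Default 2; `NULL` disables
#'   rounding.
#' @return A one-row tibble with `sensitivity_pct`, `specificity_pct`,
#'   `ppv_pct`, `npv_pct`.
#' @export
#' @examples
#' pva_metrics(confusion_matrix(tp = 481, fp = 3, fn = 235, tn = 3777))
pva_metrics <- function(cm, decimals = 2) {
  if (!inherits(cm, "pva_confusion")) {
    abort_contract("cm must be a pva_confusion")
  }
  ratio <- function(num, den) if (den > 0) 100 * num / den else NaN
  out <- tibble(
    sensitivity_pct = ratio(cm$tp, cm$tp + cm$fn),
    specificity_pct = ratio(cm$tn, cm$tn + cm$fp),
    ppv_pct = ratio(cm$tp, cm$tp + cm$fp),
    npv_pct = ratio(cm$tn, cm$tn + cm$fn)
  )
  if (!is.null(decimals)) {
    out <- mutate(out, dplyr::across(dplyr::everything(), ~ round_half_up(.x, decimals)))
  }
  out
}

#' Evaluate the detection pipeline on an annotated stream
#'
#' Runs segmentation and both detectors on `stream`, projects predicted and
#' gold events onto breaths, and returns a confusion matrix and metric set
#' per event type. Deterministic for fixed inputs.
#'
#' @param stream A [vent_stream()].
#' @param gold_events Gold annotation tibble (e.g. `sim$gold_events` or
#'   [read_events()] output).
#' @param seg_config A [seg_config()].
#' @param detector_config A [detector_config()].
#' @return An object of class `pva_evaluation`: named list (per event type)
#'   of lists with elements `confusion` (`pva_confusion`) and `metrics`
#'   (one-row tibble). Use [tidy()] for a per-type tabular view.
#' @export
#' @examples
#' sim <- simulate_ventilation(sim_config(duration_s = 120, it_rate = 0.2, seed = 3))
#' ev <- evaluate_run(sim$stream, sim$gold_events)
#' tidy(ev)
evaluate_run <- function(stream, gold_events,
                         seg_config = ventasync::seg_config(),
                         detector_config = ventasync::detector_config()) {
  breaths <- segment_breaths(stream, seg_config)
  pred <- detect_all(stream, seg_config, detector_config, breaths = breaths)
  fs <- sample_rate(stream)
  out <- purrr::map(stats::setNames(pva_event_types, pva_event_types), function(tp) {
    pl <- label_breaths(breaths, pred, tp, sample_rate_hz = fs)
    gl <- label_breaths(breaths, gold_events, tp, sample_rate_hz = fs)
    cm <- confusion(pl, gl)
    list(confusion = cm, metrics = pva_metrics(cm))
  })
  structure(out, class = "pva_evaluation", n_breaths = nrow(breaths))
}

#' @export
print.pva_evaluation <- function(x, ...) {
  cat(sprintf(
    "# Detector evaluation over %d breaths\n", attr(x, "n_breaths")
  ))
  print(tidy(x))
  invisible(x)
}
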