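# Ventilator waveform container and file IO.
#
# A vent_stream is a tibble with one row per sample and columns
# time (s), paw (cmH2O), flow (L/min), volume (mL), carrying the sample rate
# and free-form metadata as attributes. All downstream stages (segmentation,
# detection, asynchrony index) consume this container.

#' Construct a ventilator waveform stream
#'
#' Bundles synchronized airway-pressure, flow and volume samples into a
#' validated tibble. Units follow ventilator convention: `paw` in cmH2O,
#' `flow` in L/min, `volume` in mL, sampled at `sample_rate_hz` (50 Hz on the
#' ventilators this package targets).
#'
#' @param paw Numeric vector, airway pressure (cmH2O).
#' @param flow Numeric vector, flow (L/min); same length as `paw`.
#' @param volume Numeric vector, volume (mL); same length as `paw`.
#' @param sample_rate_hz Sampling frequency in Hz (default 50).
#' @param time Optional numeric vector of sample times in seconds; computed
#'   from `sample_rate_hz` when missing.
#' @param meta Named list of free-form metadata (patient id, ventilator model,
#'   ventilation mode, PEEP setting, ...).
#'
#' @return A `vent_stream`: a tibble with columns `time`, `paw`, `flow`,
#'   `volume` and attributes `sample_rate_hz` and `meta`.
#' @export
#' @examples
#' s <- vent_stream(paw = c(5, 10, 5), flow = c(0, 30, 0), volume = c(0, 300, 0))
#' sample_rate(s)
vent_stream <- function(paw, flow, volume, sample_rate_hz = 50, time = NULL,
                        meta = list()) {
  n <- length(paw)
  if (n < 1) abort_data("stream must contain at least one sample")
  if (length(flow) != n || length(volume) != n) {
    abort_data("paw, flow and volume must have identical length")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
    !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    abort_data("sample_rate_hz must be a single positive number")
  }
  if (is.null(time)) {
    time <- (seq_len(n) - 1) / sample_rate_hz
  } else if (length(time) != n) {
    abort_data("time must match the waveform length")
  }
  out <- tibble(
    time = as.double(time), paw = as.double(paw),
    flow = as.double(flow), volume = as.double(volume)
  )
  new_vent_stream(out, sample_rate_hz = sample_rate_hz, meta = meta)
}

new_vent_stream <- function(df, sample_rate_hz, meta = list()) {
  structure(
    df,
    sample_rate_hz = as.double(sample_rate_hz),
    meta = meta,
    class = c("vent_stream", class(tibble()))
  )
}

#' @export
print.vent_stream <- function(x, ...) {
  cat(sprintf(
    "# A vent_stream: %d samples at %g Hz (%.1f s)\n",
    nrow(x), sample_rate(x), nrow(x) / sample_rate(x)
  ))
  NextMethod()
}

#' Sample rate of a stream
#'
#' @param s A [vent_stream()].
#' @return Sampling frequency in Hz.
#' @export
sample_rate <- function(s) {
  r <- attr(s, "sample_rate_hz")
  if (is.null(r)) abort_contract("not a vent_stream: missing sample_rate_hz")
  r
}

#' Stream duration in seconds
#'
#' @param s A [vent_stream()].
#' @return Duration `nrow(s) / sample_rate(s)` in seconds.
#' @export
stream_duration <- function(s) nrow(s) / sample_rate(s)

#' Metadata attached to a stream
#'
#' @param s A [vent_stream()].
#' @return Named list of metadata.
#' @export
stream_meta <- function(s) attr(s, "meta") %||% list()

# assert the container is structurally valid (shape only; NaN/Inf are the
# business of clean_stream)
validate_stream_shape <- function(s) {
  cols <- c("time", "paw", "flow", "volume")
  missing_cols <- setdiff(cols, names(s))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "stream is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(s) < 1) abort_data("stream is empty")
  invisible(s)
}

#' Read a ventilator waveform stream from disk
#'
#' Reads the package's open waveform dialect: CSV with header columns
#' `time,paw,flow,volume` (`time` optional) or JSON-lines with one sample
#' object per line carrying the same keys. When a `time` column is present the
#' sample rate is inferred from the median inter-sample interval (accepted
#' when jitter is below 5%); otherwise `sample_rate_hz` is used.
#'
#' @param path Path to the waveform file.
#' @param format `"csv"` or `"jsonl"`; default guesses from the file
#'   extension.
#' @param sample_rate_hz Sample rate to assume when the file has no time
#'   column (default 50 Hz).
#' @param meta Metadata list attached to the returned stream.
#'
#' @return A validated [vent_stream()].
#' @export
read_vent_stream <- function(path, format = c("auto", "csv", "jsonl"),
                             sample_rate_hz = 50, meta = list()) {
  format <- arg_match(format)
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- switch(format,
    csv = {
      out <- tryCatch(
        readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
        error = function(e) abort_format(paste0("cannot parse CSV: ", conditionMessage(e)))
      )
      out
    },
    jsonl = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0) abort_data("empty file")
      rows <- tryCatch(
        purrr::map(lines, jsonlite::fromJSON),
        error = function(e) abort_format(paste0("cannot parse JSONL: ", conditionMessage(e)))
      )
      bind_rows(purrr::map(rows, as_tibble))
    }
  )
  if (nrow(df) == 0) abort_data("empty file")
  required <- c("paw", "flow", "volume")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "waveform file is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if ("time" %in% names(df)) {
    tm <- as.double(df$time)
    if (nrow(df) >= 2) {
      dts <- diff(tm)
      if (any(dts <= 0)) abort_data("time column is not strictly increasing")
      dt <- median(dts)
      if (max(abs(dts - dt)) > 0.05 * dt) {
        abort_data("inter-sample jitter exceeds 5%; cannot infer sample rate")
      }
      sample_rate_hz <- 1 / dt
    }
    vent_stream(df$paw, df$flow, df$volume,
      sample_rate_hz = sample_rate_hz, time = tm, meta = meta
    )
  } else {
    vent_stream(df$paw, df$flow, df$volume,
      sample_rate_hz = sample_rate_hz, meta = meta
    )
  }
}

#' Write a ventilator waveform stream to disk
#'
#' @param s A [vent_stream()].
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_vent_stream <- function(s, path, format = c("csv", "jsonl")) {
  format <- arg_match(format)
  validate_stream_shape(s)
  df <- as_tibble(s)[, c("time", "paw", "flow", "volume")]
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Clean a waveform stream
#'
#' Replaces or rejects non-finite samples (NaN/Inf/NA) and optionally applies
#' moving-average smoothing. Under `policy = "interpolate"` non-finite runs are
#' filled by linear interpolation (constant extrapolation at the edges); the
#' stream is rejected as unusable when more than 10% of samples in any channel
#' are invalid (a single invalid sample is always tolerated, so very short
#' streams remain repairable). `clean_stream` is idempotent when smoothing is
#' off.
#'
#' @param s A [vent_stream()].
#' @param policy `"interpolate"` (default) or `"reject"` (error on any
#'   non-finite sample).
#' @param max_invalid_frac Maximum tolerated fraction of invalid samples per
#'   channel under `interpolate` (default 0.1).
#' @param smooth_window Odd moving-average window length in samples; `NULL`
#'   (default) disables smoothing.
#'
#' @return A cleaned [vent_stream()] with all samples finite.
#' @export
#' @examples
#' s <- vent_stream(paw = c(5, 6, 5), flow = c(0, NaN, 10), volume = c(0, 1, 2))
#' clean_stream(s)$flow # 0 5 10
clean_stream <- function(s, policy = c("interpolate", "reject"),
                         max_invalid_frac = 0.1, smooth_window = NULL) {
  policy <- arg_match(policy)
  validate_stream_shape(s)
  out <- as_tibble(s)
  for (ch in c("paw", "flow", "volume")) {
    x <- out[[ch]]
    bad <- !is.finite(x)
    if (any(bad)) {
      if (policy == "reject") {
        abort_data(paste0("non-finite samples in channel '", ch, "'"))
      }
      if (sum(bad) > max(1, max_invalid_frac * length(x))) {
        abort_data(paste0(
          "channel '", ch, "' has ", sprintf("%.1f%%", 100 * mean(bad)),
          " invalid samples (> ", sprintf("%.0f%%", 100 * max_invalid_frac),
          "); signal unusable"
        ))
      }
      if (all(bad)) abort_data(paste0("channel '", ch, "' is entirely invalid"))
      good <- which(!bad)
      x <- approx(good, x[good], xout = seq_along(x), rule = 2)$y
    }
    if (!is.null(smooth_window) && smooth_window > 1) {
      x <- moving_average(x, smooth_window)
    }
    out[[ch]] <- x
  }
  new_vent_stream(out, sample_rate_hz = sample_rate(s), meta = stream_meta(s))
}
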