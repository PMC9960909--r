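# Asynchrony event tables and their CSV round trip.
#
# Events — detected or gold-standard — are plain tibbles with columns
# event_type ("double_trigger" | "ineffective_trigger"), sample_index
# (1-based, within the owning stream), optional end_index, and source
# ("gold" | "predicted"). Detector output adds per-event feature columns.

pva_event_types <- c("double_trigger", "ineffective_trigger")

#' Build an event annotation table
#'
#' @param event_type Character vector of event types
#'   (`"double_trigger"` or `"ineffective_trigger"`).
#' @param sample_index Integer vector of 1-based sample indices.
#' @param end_index Optional integer vector of 1-based end indices
#'   (`NA` where not applicable); must be `>= sample_index`.
#' @param source `"gold"` or `"predicted"` (recycled).
#'
#' @return A tibble with columns `event_type`, `sample_index`, `end_index`,
#'   `source`, sorted by `sample_index`.
#' @export
#' @examples
#' pva_events("ineffective_trigger", sample_index = 120, source = "gold")
pva_events <- function(event_type = character(), sample_index = integer(),
                       end_index = NA_integer_, source = "predicted") {
  if (length(event_type) != length(sample_index)) {
    abort_contract("event_type and sample_index must have equal length")
  }
  bad <- setdiff(unique(event_type), pva_event_types)
  if (length(bad) > 0) {
    abort_format(paste0("unknown event_type: ", paste(bad, collapse = ", ")))
  }
  if (any(sample_index < 1, na.rm = TRUE)) {
    abort_contract("sample_index must be >= 1")
  }
  out <- tibble(
    event_type = as.character(event_type),
    sample_index = as.integer(sample_index),
    end_index = as.integer(rep_len(end_index, length(event_type))),
    source = as.character(rep_len(source, length(event_type)))
  )
  if (any(!is.na(out$end_index) & out$end_index < out$sample_index)) {
    abort_contract("end_index must be >= sample_index")
  }
  arrange(out, .data$sample_index)
}

#' Write events to CSV
#'
#' Writes the events CSV dialect (header
#' `event_type,sample_index,end_index,source`), sorted by `sample_index`.
#' `read_events(write_events(e, path))` round-trips exactly.
#'
#' @param events Event tibble as returned by [pva_events()] or the detectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("event_type", "sample_index", "end_index", "source")
  missing_cols <- setdiff(cols, names(events))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "events table missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  out <- arrange(as_tibble(events)[, cols], .data$sample_index)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read events from CSV
#'
#' @param path Path to an events CSV written by [write_events()].
#' @return Event tibble with columns `event_type`, `sample_index`,
#'   `end_index`, `source`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_data(paste0("file not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_format(paste0("cannot parse events CSV: ", conditionMessage(e)))
  )
  missing_cols <- setdiff(
    c("event_type", "sample_index", "end_index", "source"), names(df)
  )
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "events CSV missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  pva_events(df$event_type, df$sample_index, df$end_index, df$source)
}
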