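# Shared numeric helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 67.175 -> 67.18), matching how diagnostic metrics are conventionally
#' printed, rather than base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly .5 in decimal but
  # stored fractionally below it (e.g. 481/716*100) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Centred moving average; window must be odd. Edges use shrinking windows so
# the output has the same length and no NA padding.
moving_average <- function(x, window) {
  if (window <= 1) {
    return(x)
  }
  stopifnot(window %% 2 == 1)
  half <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

abort_data <- function(msg) abort(msg, class = "ventasync_data_error")
abort_format <- function(msg) abort(msg, class = "ventasync_format_error")
abort_contract <- function(msg) abort(msg, class = "ventasync_contract_error")
abort_config <- function(msg) abort(msg, class = "ventasync_config_error")
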