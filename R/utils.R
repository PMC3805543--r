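# Shared numeric helpers. All sample indices in this package are 1-based and
# intervals are half-open [onset, offset) in sample units.

# round half away from zero (base round() is banker's)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Convert a duration in milliseconds to a whole number of samples
#'
#' Uses round-half-away-from-zero, so 128 ms at 367 Hz gives 47 samples.
#'
#' @param ms Duration in milliseconds.
#' @param fs Sampling frequency in Hz.
#' @return Integer number of samples (at least 1 for positive `ms`).
#' @export
ms_to_samples <- function(ms, fs) {
  stopifnot(is.numeric(ms), is.numeric(fs), fs > 0)
  as.integer(round_half_away(ms * fs / 1000))
}

#' Moving-average window length in samples (nearest odd integer)
#'
#' The event-related moving averages use windows rounded to the nearest odd
#' number of samples so the window has a well-defined centre sample:
#' 111 ms at 367 Hz gives 41 samples, 667 ms gives 245.
#'
#' @inheritParams ms_to_samples
#' @return Odd integer window length.
#' @export
ma_window_samples <- function(ms, fs) {
  stopifnot(ms > 0, fs > 0)
  w <- ms * fs / 1000
  # nearest odd integer; exact ties resolve away from zero
  as.integer(2 * round_half_away((w - 1) / 2) + 1)
}

validation_error <- function(msg, ...) {
  abort(msg, class = "ppgpeaks_validation_error", ...)
}

parse_error <- function(msg, ...) {
  abort(msg, class = "ppgpeaks_parse_error", ...)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    validation_error(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    validation_error(sprintf("`%s` must be > %g", name, lower))
  }
  if (x < lower || x > upper) {
    validation_error(sprintf("`%s` must be in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}
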