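# Signal-conditioning primitives shared by all detectors. Every stage is
# length-preserving and takes / returns a ppg_record tibble, so stages chain
# with the pipe:
#
#   rec |> butter_zero_phase(low_hz = 0.5, high_hz = 8) |>
#     clip_above_zero() |> square_signal() |> moving_average(111)

# steady-state initial conditions for a step input (scipy lfilter_zi analogue):
# filtering a constant x0 from state zi * x0 yields the constant H(1) * x0
# with no transient.
filter_steady_state <- function(b, a, x) {
  g <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
    init.x = rep(x[1], length(b) - 1L),
    init.y = rep(x[1] * g, length(a) - 1L)
  ))
}

#' Zero-phase Butterworth filter
#'
#' Designs an order-`order` Butterworth filter (`signal::butter`) and applies
#' it forward and backward, which cancels the phase response (effective order
#' `2 * order`, zero lag). Edge transients are controlled by odd-reflection
#' padding of three periods of the lowest corner frequency plus steady-state
#' filter initialisation, so a constant input maps to an exactly constant
#' output (zero, for a bandpass).
#'
#' @param x A `ppg_record` (any stage).
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param low_hz Low corner in Hz (bandpass only).
#' @param high_hz High corner in Hz. Must be below the Nyquist frequency.
#' @param order Per-direction design order (default 2).
#' @return A `ppg_record` at stage `"filtered"`.
#' @examples
#' rec <- ppg_record(sin(2 * pi * 4 * seq(0, 20, by = 1 / 367)), fs = 367)
#' filt <- butter_zero_phase(rec, "bandpass", 0.5, 8)
#' @export
butter_zero_phase <- function(x, kind = c("bandpass", "lowpass"),
                              low_hz = 0.5, high_hz = 8, order = 2) {
  kind <- match.arg(kind)
  fs <- ppg_fs(x)
  nyq <- fs / 2
  check_scalar_number(high_hz, "high_hz", lower = 0, strict_lower = TRUE)
  if (high_hz >= nyq) {
    validation_error(sprintf("high_hz (%g) must be below Nyquist (%g Hz)",
                             high_hz, nyq))
  }
  if (kind == "bandpass") {
    check_scalar_number(low_hz, "low_hz", lower = 0, strict_lower = TRUE)
    if (low_hz >= high_hz) {
      validation_error("low_hz must be below high_hz")
    }
    bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
    corner <- low_hz
  } else {
    bf <- signal::butter(order, high_hz / nyq, type = "low")
    corner <- high_hz
  }
  n <- nrow(x)
  npad <- as.integer(round(3 * fs / corner))
  if (n <= npad) {
    validation_error(sprintf(
      "record too short for zero-phase filtering: %d samples <= padding length %d (3 periods of the %g Hz corner)",
      n, npad, corner))
  }
  sig <- x$amplitude
  pre <- 2 * sig[1] - sig[(npad + 1):2]
  post <- 2 * sig[n] - sig[(n - 1):(n - npad)]
  xe <- c(pre, sig, post)
  y1 <- filter_steady_state(bf$b, bf$a, xe)
  y2 <- rev(filter_steady_state(bf$b, bf$a, rev(y1)))
  record_like(x, y2[(npad + 1):(npad + n)], stage = "filtered")
}

#' Half-wave rectification: keep the signal above zero
#' @param x A `ppg_record`.
#' @return A `ppg_record` at stage `"clipped"` with `amplitude = pmax(x, 0)`.
#' @export
clip_above_zero <- function(x) {
  record_like(x, pmax(x$amplitude, 0), stage = "clipped")
}

#' Elementwise squaring
#'
#' Squaring the clipped signal emphasises the large-amplitude systolic
#' excursions over the smaller diastolic wave and noise.
#'
#' @param x A `ppg_record` (intended for a clipped, non-negative signal).
#' @return A `ppg_record` at stage `"squared"`.
#' @export
square_signal <- function(x) {
  record_like(x, x$amplitude^2, stage = "squared")
}

# core centered moving average on a plain numeric vector; truncated-window
# means at the edges (no padding), O(n) via cumulative sums
moving_average_num <- function(v, w) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(v)
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Centered moving average with an event-scale window
#'
#' The window length is the duration in milliseconds converted to the nearest
#' odd number of samples (`ma_window_samples()`), so the average is centered
#' on each sample and introduces no lag. Edges use the truncated (shrunken)
#' window mean rather than padded data.
#'
#' @param x A `ppg_record`.
#' @param window_ms Window duration in milliseconds (> 0). 111 ms targets the
#'   systolic-peak duration, 667 ms a full beat.
#' @param stage Stage label for the output.
#' @return A `ppg_record` of the same length.
#' @export
moving_average <- function(x, window_ms, stage = "ma") {
  fs <- ppg_fs(x)
  check_scalar_number(window_ms, "window_ms", lower = 0, strict_lower = TRUE)
  w <- ma_window_samples(window_ms, fs)
  if (w > nrow(x)) {
    validation_error(sprintf("window of %d samples exceeds record length %d",
                             w, nrow(x)))
  }
  record_like(x, moving_average_num(x$amplitude, w), stage = stage)
}

#' First difference, length-preserving
#'
#' `out[n] = x[n] - x[n-1]` for `n >= 2`; `out[1] = 0`. The first sample never
#' hosts a peak decision, so zero-padding there is harmless.
#'
#' @param x A `ppg_record` of length >= 2.
#' @return A `ppg_record` at stage `"derivative"`.
#' @export
first_difference <- function(x) {
  if (nrow(x) < 2) validation_error("first_difference needs length >= 2")
  record_like(x, c(0, diff(x$amplitude)), stage = "derivative")
}

#' Slope sum function (SSF)
#'
#' Windowed sum of positive first differences:
#' `SSF[n] = sum_{k = n-w+1..n} max(x[k] - x[k-1], 0)`, with the first `w`
#' samples computed over the available (truncated) history so the output
#' length equals the input length. The SSF amplifies the steep systolic
#' upslope of each pulse and suppresses the rest of the waveform.
#'
#' @param x A `ppg_record`.
#' @param window_ms Analysis window in milliseconds; the default 128 ms is
#'   47 samples at 367 Hz.
#' @return A non-negative `ppg_record` at stage `"ssf"`.
#' @export
slope_sum <- function(x, window_ms = 128) {
  fs <- ppg_fs(x)
  w <- ms_to_samples(window_ms, fs)
  if (w < 1) validation_error("window_ms too small: zero samples")
  n <- nrow(x)
  if (n <= w) {
    validation_error(sprintf("record length %d must exceed SSF window %d", n, w))
  }
  u <- c(0, pmax(diff(x$amplitude), 0))
  cs <- cumsum(u)
  lo <- pmax(seq_len(n) - w + 1L, 1L)
  out <- cs - c(0, cs)[lo]  # sum over (lo-1, n] of u = positive slopes in window
  # guard tiny negative rounding residue
  record_like(x, pmax(out, 0), stage = "ssf")
}
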