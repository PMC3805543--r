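# Event-related dual moving-average detector with a dynamic offset threshold.
#
# Stages: bandpass 0.5-8 Hz (zero phase) -> clip above zero -> square ->
# two moving averages at systolic (W1) and beat (W2) scale -> blocks of
# interest where MApeak exceeds MAbeat + beta * mean(squared) -> reject
# blocks narrower than W1 -> peak = argmax of the squared signal per block.

#' Parameters for the dual moving-average detector
#'
#' @param f1,f2 Bandpass corners in Hz (defaults 0.5 and 8).
#' @param w1_ms Systolic-scale moving-average window in ms (default 111).
#' @param w2_ms Beat-scale moving-average window in ms (default 667).
#' @param beta Offset fraction of the mean squared signal (default 0.02).
#' @return An `elgendi_params` list.
#' @export
elgendi_params <- function(f1 = 0.5, f2 = 8, w1_ms = 111, w2_ms = 667,
                           beta = 0.02) {
  check_scalar_number(f1, "f1", lower = 0, strict_lower = TRUE)
  check_scalar_number(f2, "f2", lower = 0, strict_lower = TRUE)
  if (f1 >= f2) validation_error("f1 must be below f2")
  check_scalar_number(w1_ms, "w1_ms", lower = 0, strict_lower = TRUE)
  check_scalar_number(w2_ms, "w2_ms", lower = 0, strict_lower = TRUE)
  if (w1_ms >= w2_ms) validation_error("w1_ms must be below w2_ms")
  check_scalar_number(beta, "beta", lower = 0)
  structure(list(f1 = f1, f2 = f2, w1_ms = w1_ms, w2_ms = w2_ms, beta = beta),
            class = "elgendi_params")
}

#' Blocks of interest from the two moving averages
#'
#' Maximal runs of samples where the systolic-scale average strictly exceeds
#' the dynamic threshold, returned as half-open `[onset, offset)` intervals.
#'
#' @param ma_peak,thr1 Numeric vectors (or `ppg_record`s) of equal length.
#' @return A tibble with columns `onset`, `offset` (1-based, half-open),
#'   in increasing order, non-overlapping.
#' @export
generate_blocks <- function(ma_peak, thr1) {
  a <- if (is.data.frame(ma_peak)) ma_peak$amplitude else as.numeric(ma_peak)
  b <- if (is.data.frame(thr1)) thr1$amplitude else as.numeric(thr1)
  if (length(a) != length(b)) {
    validation_error("ma_peak and thr1 must have equal length")
  }
  above <- a > b
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(onset = starts[keep], offset = ends[keep] + 1L)
}

#' Reject blocks narrower than the expected systolic duration
#'
#' @param blocks A tibble of half-open blocks (`onset`, `offset`).
#' @param thr2_samples Minimum accepted width in samples (>= 1); blocks with
#'   `offset - onset >= thr2_samples` survive.
#' @return The surviving blocks.
#' @export
reject_blocks <- function(blocks, thr2_samples) {
  check_scalar_number(thr2_samples, "thr2_samples", lower = 1)
  blocks[blocks$offset - blocks$onset >= thr2_samples, , drop = FALSE]
}

#' Detect systolic peaks with two event-related moving averages
#'
#' The detector bandpass-filters the record (zero phase), clips it above
#' zero, squares it, and smooths the squared signal at two scales: a
#' systolic-duration window `W1` and a beat-duration window `W2`. Samples
#' where the `W1` average exceeds the `W2` average plus an offset
#' `alpha = beta * mean(squared signal)` form candidate blocks; blocks
#' narrower than `W1` samples are rejected as noise or diastolic activity,
#' and each surviving block contributes the argmax of the squared signal as
#' a systolic peak. Because every threshold is built from moving averages of
#' the signal itself, the detector is invariant to positive amplitude
#' scaling.
#'
#' @param record A `ppg_record`.
#' @param params An [elgendi_params()] bundle.
#' @return A `peak_annotation` of detected systolic peaks.
#' @examples
#' s <- synth_ppg(synth_preset("rest", noise_sd = 0, seed = 1))
#' det <- detect_elgendi(s$record)
#' match_peaks(s$truth, det)
#' @export
detect_elgendi <- function(record, params = elgendi_params()) {
  if (!inherits(params, "elgendi_params")) {
    params <- do.call(elgendi_params, as.list(params))
  }
  fs <- ppg_fs(record)
  w1 <- ma_window_samples(params$w1_ms, fs)
  w2 <- ma_window_samples(params$w2_ms, fs)
  if (nrow(record) < w2) {
    validation_error("record shorter than the beat-scale window W2")
  }
  z <- record |>
    butter_zero_phase("bandpass", params$f1, params$f2) |>
    clip_above_zero() |>
    square_signal()
  ma_peak <- moving_average_num(z$amplitude, w1)
  ma_beat <- moving_average_num(z$amplitude, w2)
  alpha <- params$beta * mean(z$amplitude)
  thr1 <- ma_beat + alpha
  blocks <- generate_blocks(ma_peak, thr1)
  blocks <- reject_blocks(blocks, w1)  # THR2 = W1 in samples
  peaks <- purrr::map2_int(blocks$onset, blocks$offset, function(on, off) {
    seg <- z$amplitude[on:(off - 1L)]
    on + which.max(seg) - 1L  # ties resolve to the earliest sample
  })
  peak_annotation(peaks, fs = fs, n_samples = nrow(record))
}
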