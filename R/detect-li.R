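# First-derivative delineator with adaptive amplitude and interval
# thresholds (Li-style). The derivative acts as a high-pass stage, so only a
# low-pass filter precedes it; systolic peaks sit at negative-going zero
# crossings of the derivative that follow a maximal inflection.

#' Parameters for the first-derivative delineator
#'
#' The source method leaves several constants unstated; the defaults below
#' are package choices, exposed so they can be varied.
#'
#' @param lowpass_hz Low-pass corner in Hz (default 8, the passband ceiling
#'   used elsewhere in the package).
#' @param n_divisions Number of equal record divisions whose leading
#'   selective windows seed the initial thresholds (default 3).
#' @param selective_window_s Duration of each selective window in seconds
#'   (default 2).
#' @param amplitude_factor Fraction of the averaged selective-window
#'   derivative maximum used as the amplitude threshold (default 0.5).
#' @param interval_factor_low,interval_factor_high Multiples of the running
#'   beat interval bounding an acceptable new interval (defaults 0.5, 1.5).
#'   Candidates closer than `interval_factor_low` times the running interval
#'   to the previous beat are rejected; intervals inside the band update the
#'   running estimate.
#' @return A `li_params` list.
#' @export
li_params <- function(lowpass_hz = 8, n_divisions = 3, selective_window_s = 2,
                      amplitude_factor = 0.5, interval_factor_low = 0.5,
                      interval_factor_high = 1.5) {
  check_scalar_number(lowpass_hz, "lowpass_hz", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_divisions, "n_divisions", lower = 1)
  check_scalar_number(selective_window_s, "selective_window_s",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(amplitude_factor, "amplitude_factor",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(interval_factor_low, "interval_factor_low",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(interval_factor_high, "interval_factor_high",
                      lower = interval_factor_low, strict_lower = TRUE)
  structure(list(lowpass_hz = lowpass_hz,
                 n_divisions = as.integer(n_divisions),
                 selective_window_s = selective_window_s,
                 amplitude_factor = amplitude_factor,
                 interval_factor_low = interval_factor_low,
                 interval_factor_high = interval_factor_high),
            class = "li_params")
}

# local maxima of a numeric vector (strict rise, fall-or-equal), interior only
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] >= v[i + 1]]
}

# negative-going zero crossings of d at or after position i (first k >= i
# with d[k] > 0 and d[k + 1] <= 0); returns NA when none exists
next_neg_crossing <- function(d, i) {
  n <- length(d)
  k <- i
  while (k < n && !(d[k] > 0 && d[k + 1] <= 0)) k <- k + 1L
  if (k >= n) NA_integer_ else k
}

#' Detect systolic peaks with a first-derivative delineator
#'
#' The record is low-pass filtered (zero phase) and differenced. Maximal
#' inflections -- local maxima of the derivative exceeding an adaptive
#' amplitude threshold -- mark candidate upslopes; the following
#' negative-going zero crossing of the derivative is the systolic-peak
#' candidate. Amplitude and interval thresholds are initialised from 2 s
#' selective windows at the start of each of `n_divisions` equal divisions
#' of the record, then updated beat-by-beat as running means over accepted
#' beats. Candidates closer to the previous accepted beat than
#' `interval_factor_low` times the running beat interval are rejected.
#'
#' @param record A `ppg_record` at least one selective window long.
#' @param params A [li_params()] bundle.
#' @return A `peak_annotation`.
#' @export
detect_li <- function(record, params = li_params()) {
  if (!inherits(params, "li_params")) {
    params <- do.call(li_params, as.list(params))
  }
  fs <- ppg_fs(record)
  n <- nrow(record)
  win <- as.integer(round(params$selective_window_s * fs))
  if (n < win) {
    validation_error("record shorter than one selective window")
  }
  filt <- butter_zero_phase(record, "lowpass", high_hz = params$lowpass_hz)
  d <- c(0, diff(filt$amplitude))

  # ---- threshold initialisation from selective windows ----
  div_len <- n %/% params$n_divisions
  starts <- 1L + (seq_len(params$n_divisions) - 1L) * div_len
  amp_est <- numeric(0)
  int_est <- numeric(0)
  for (s in starts) {
    e <- min(s + win - 1L, n)
    dw <- d[s:e]
    dmax <- max(dw)
    if (dmax <= 0) next
    amp_est <- c(amp_est, dmax)
    # rough in-window beat positions: negative-going crossings preceded by a
    # strong upslope; their spacing estimates the pulse interval
    lm <- local_maxima(dw)
    lm <- lm[dw[lm] > 0.5 * dmax]
    cr <- integer(0)
    for (i in lm) {
      k <- next_neg_crossing(dw, i)
      if (!is.na(k)) cr <- c(cr, k)
    }
    cr <- unique(cr)
    if (length(cr) >= 2) int_est <- c(int_est, diff(cr))
  }
  if (length(amp_est) == 0) {
    # no upslopes anywhere (e.g. flat line): nothing to detect
    return(peak_annotation(integer(0), fs = fs, n_samples = n))
  }
  thr_amp <- params$amplitude_factor * mean(amp_est)
  rr <- if (length(int_est) > 0) mean(int_est) else 60 / 76 * fs

  # ---- beat-by-beat search ----
  infl <- local_maxima(d)
  infl <- infl[d[infl] > 0]
  peaks <- integer(0)
  d_amps <- numeric(0)
  last_peak <- NA_integer_
  for (i in infl) {
    if (d[i] <= thr_amp) next
    k <- next_neg_crossing(d, i)
    if (is.na(k)) next
    # derivative crosses zero between k and k+1; take the larger sample
    cand <- if (filt$amplitude[min(k + 1L, n)] > filt$amplitude[k]) k + 1L else k
    if (length(peaks) > 0 && cand == peaks[length(peaks)]) next
    if (!is.na(last_peak)) {
      gap <- cand - last_peak
      if (gap < params$interval_factor_low * rr) {
        # too close to the previous beat: keep whichever upslope is steeper
        if (d[i] > d_amps[length(d_amps)]) {
          peaks[length(peaks)] <- cand
          d_amps[length(d_amps)] <- d[i]
          last_peak <- cand
        }
        next
      }
      if (gap >= params$interval_factor_low * rr &&
          gap <= params$interval_factor_high * rr) {
        rr <- 0.8 * rr + 0.2 * gap
      }
    }
    peaks <- c(peaks, cand)
    d_amps <- c(d_amps, d[i])
    last_peak <- cand
    thr_amp <- 0.8 * thr_amp + 0.2 * params$amplitude_factor * d[i]
  }
  peak_annotation(peaks, fs = fs, n_samples = n)
}
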