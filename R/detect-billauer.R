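# Local maxima / minima peak picking with an absolute amplitude delta
# (Billauer-style alternating peak/valley state machine).

#' Parameters for the local-extrema detector
#'
#' @param delta Amplitude excursion (same units as the processed signal) that
#'   must be crossed before an extremum is committed; default 0.1, which
#'   presumes signals on the order of unit amplitude.
#' @param use_bandpass Apply the 0.5-8 Hz zero-phase bandpass before peak
#'   picking (default `TRUE`); disable to recover the unfiltered original
#'   behaviour.
#' @param f1,f2 Bandpass corners in Hz.
#' @param normalize Rescale the processed signal to unit maximum absolute
#'   amplitude before applying `delta`. Default `FALSE`: `delta` is absolute,
#'   so the detector is deliberately not amplitude-scale invariant.
#' @return A `billauer_params` list.
#' @export
billauer_params <- function(delta = 0.1, use_bandpass = TRUE,
                            f1 = 0.5, f2 = 8, normalize = FALSE) {
  check_scalar_number(delta, "delta", lower = 0, strict_lower = TRUE)
  structure(list(delta = delta, use_bandpass = isTRUE(use_bandpass),
                 f1 = f1, f2 = f2, normalize = isTRUE(normalize)),
            class = "billauer_params")
}

# alternating extremum search: commit the running maximum as a peak once the
# signal has dropped delta below it, then hunt the next valley, and so on
billauer_state_machine <- function(v, delta) {
  n <- length(v)
  peaks <- integer(0)
  mx <- -Inf; mn <- Inf
  mxpos <- NA_integer_
  look_for_max <- TRUE
  for (i in seq_len(n)) {
    s <- v[i]
    if (s > mx) { mx <- s; mxpos <- i }
    if (s < mn) { mn <- s }
    if (look_for_max) {
      if (s < mx - delta) {
        peaks <- c(peaks, mxpos)
        mn <- s
        look_for_max <- FALSE
      }
    } else {
      if (s > mn + delta) {
        mx <- s; mxpos <- i
        look_for_max <- TRUE
      }
    }
  }
  peaks
}

#' Detect systolic peaks by local maxima and minima
#'
#' Tracks the running maximum of the (optionally bandpass-filtered) signal;
#' when the signal falls more than `delta` below the running maximum, that
#' maximum is committed as a peak and the search flips to valley hunting
#' (symmetric rule). Only the peaks are returned. `delta` is an absolute
#' amplitude, so on clean unit-scale PPG it separates systolic peaks from
#' the smaller diastolic wave, but the detector is not scale invariant.
#'
#' @param record A `ppg_record` of length >= 3.
#' @param params A [billauer_params()] bundle.
#' @return A `peak_annotation`.
#' @export
detect_billauer <- function(record, params = billauer_params()) {
  if (!inherits(params, "billauer_params")) {
    params <- do.call(billauer_params, as.list(params))
  }
  if (nrow(record) < 3) validation_error("record must have length >= 3")
  x <- record
  if (params$use_bandpass) {
    x <- butter_zero_phase(x, "bandpass", params$f1, params$f2)
  }
  v <- x$amplitude
  if (params$normalize) {
    m <- max(abs(v))
    if (m > 0) v <- v / m
  }
  peaks <- billauer_state_machine(v, params$delta)
  peak_annotation(peaks, fs = ppg_fs(record), n_samples = nrow(record))
}
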