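# Slope-sum detector with an adaptive threshold (Zong-style). The slope sum
# amplifies each pulse upslope; pulses are found as upward threshold
# crossings of the SSF, then mapped to systolic peaks on the band-limited
# signal so the output is comparable with systolic-peak annotations.

#' Parameters for the slope-sum detector
#'
#' @param ssf_window_ms Slope-sum window in ms (default 128; 47 samples at
#'   367 Hz).
#' @param init_seconds Seconds of SSF used to initialise the threshold base
#'   (default 8; base = 3 x mean SSF over this span).
#' @param threshold_fraction Fraction of the base forming the actual
#'   crossing threshold (default 0.60).
#' @param search_ms Min/max search window on either side of a crossing in ms
#'   (default 150).
#' @param onset_fraction Fraction of the pulse maximum defining the pulse
#'   onset during the backward search (default 0.01).
#' @param phase_adjust_ms Backward onset shift compensating the low-pass
#'   phase (default 20).
#' @param refractory_ms Eye-closing period after an accepted pulse during
#'   which no new detection starts (default 300).
#' @param lowpass_hz Low-pass corner preceding the SSF in Hz (default 16, a
#'   package choice preserving the pulse upslope).
#' @param accept_min_excursion_fraction Minimum SSF min-to-max excursion
#'   around a crossing, as a fraction of the threshold base, for the pulse
#'   to be accepted (default 0.10, a package choice).
#' @return A `zong_params` list.
#' @export
zong_params <- function(ssf_window_ms = 128, init_seconds = 8,
                        threshold_fraction = 0.60, search_ms = 150,
                        onset_fraction = 0.01, phase_adjust_ms = 20,
                        refractory_ms = 300, lowpass_hz = 16,
                        accept_min_excursion_fraction = 0.10) {
  for (nm in c("ssf_window_ms", "init_seconds", "search_ms",
               "phase_adjust_ms", "refractory_ms", "lowpass_hz")) {
    check_scalar_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  for (nm in c("threshold_fraction", "onset_fraction",
               "accept_min_excursion_fraction")) {
    v <- get(nm)
    check_scalar_number(v, nm, lower = 0, upper = 1, strict_lower = TRUE)
    if (v >= 1) validation_error(sprintf("`%s` must be below 1", nm))
  }
  structure(list(ssf_window_ms = ssf_window_ms, init_seconds = init_seconds,
                 threshold_fraction = threshold_fraction, search_ms = search_ms,
                 onset_fraction = onset_fraction,
                 phase_adjust_ms = phase_adjust_ms,
                 refractory_ms = refractory_ms, lowpass_hz = lowpass_hz,
                 accept_min_excursion_fraction = accept_min_excursion_fraction),
            class = "zong_params")
}

#' Detect systolic peaks with the slope-sum function
#'
#' The record is low-pass filtered (zero phase) and transformed with
#' [slope_sum()]. The threshold base is initialised to three times the mean
#' SSF over the first `init_seconds`; the actual threshold is 60% of the
#' base. At each upward crossing the SSF minimum in the preceding and
#' maximum in the following `search_ms` window are located; the pulse is
#' accepted if their difference exceeds
#' `accept_min_excursion_fraction * base`, which then updates the base to
#' the pulse maximum. The pulse onset is the latest sample before the
#' crossing where the SSF still exceeds `onset_fraction` of the pulse
#' maximum, shifted `phase_adjust_ms` earlier; the reported systolic peak is
#' the argmax of the filtered signal within `2 * search_ms` after the onset.
#' No new crossing is considered within `refractory_ms` of the previous
#' accepted pulse.
#'
#' @param record A `ppg_record` longer than `init_seconds`.
#' @param params A [zong_params()] bundle.
#' @return A `peak_annotation`.
#' @export
detect_zong <- function(record, params = zong_params()) {
  if (!inherits(params, "zong_params")) {
    params <- do.call(zong_params, as.list(params))
  }
  fs <- ppg_fs(record)
  n <- nrow(record)
  n_init <- as.integer(round(params$init_seconds * fs))
  if (n <= n_init) {
    validation_error("record shorter than the threshold initialisation span")
  }
  filt <- butter_zero_phase(record, "lowpass", high_hz = params$lowpass_hz)
  ssf <- slope_sum(filt, params$ssf_window_ms)$amplitude

  search_n <- ms_to_samples(params$search_ms, fs)
  phase_n <- ms_to_samples(params$phase_adjust_ms, fs)
  refr_n <- ms_to_samples(params$refractory_ms, fs)

  base <- 3 * mean(ssf[seq_len(n_init)])
  thr <- params$threshold_fraction * base
  peaks <- integer(0)
  last_cross <- -Inf
  i <- 2L
  while (i <= n) {
    if (ssf[i] > thr && ssf[i - 1] <= thr && (i - last_cross) >= refr_n) {
      lo <- max(1L, i - search_n)
      hi <- min(n, i + search_n)
      ssf_min <- min(ssf[lo:i])
      ssf_max <- max(ssf[i:hi])
      excursion_ok <- ssf_max > ssf_min &&
        (ssf_max - ssf_min) >= params$accept_min_excursion_fraction * base
      if (excursion_ok) {
        # backward search for the onset of the SSF pulse; bounded to the
        # min-search window so residual baseline-wander SSF cannot drag the
        # onset into the preceding beat
        onset <- i
        floor_level <- params$onset_fraction * ssf_max
        while (onset > max(1L, i - search_n) && ssf[onset - 1L] > floor_level) {
          onset <- onset - 1L
        }
        onset <- max(1L, onset - phase_n)
        win_hi <- min(n, onset + 2L * search_n)
        seg <- filt$amplitude[onset:win_hi]
        peaks <- c(peaks, onset + which.max(seg) - 1L)
        base <- ssf_max
        thr <- params$threshold_fraction * base
        last_cross <- i
      }
    }
    i <- i + 1L
  }
  ann <- peak_annotation(peaks, fs = fs, n_samples = n)
  # the refractory period acts on SSF crossings; enforce the same minimum
  # spacing on the mapped peaks so no pulse is reported twice
  idx <- peak_indices(ann)
  if (length(idx) > 1) {
    keep <- c(TRUE, diff(idx) >= refr_n)
    idx <- idx[keep]
  }
  peak_annotation(idx, fs = fs, n_samples = n)
}
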