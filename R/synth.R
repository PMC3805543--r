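# Ground-truthed synthetic PPG generator. Each beat is a systolic Gaussian
# bump plus a delayed, smaller diastolic Gaussian; beat-to-beat interval
# jitter, slow amplitude drift, sudden amplitude drops, premature beats,
# baseline wander and additive white noise emulate resting and
# post-exercise fingertip recordings. The systolic apex of every beat
# (including premature beats) is recorded pre-noise as ground truth.

#' Synthetic PPG configuration
#'
#' Defaults describe a 20 s resting recording at 367 Hz with a 76 bpm mean
#' heart rate. Use [synth_preset()] for the rest / after-exercise bundles.
#'
#' @param fs Sampling frequency in Hz (default 367).
#' @param duration_s Record duration in seconds (default 20).
#' @param hr_bpm Mean heart rate in beats per minute (default 76).
#' @param hr_jitter_frac Uniform fractional beat-interval jitter
#'   (default 0.03).
#' @param systolic_width_ms Systolic bump width in ms (default 150),
#'   interpreted as the 2-sigma full width of the Gaussian (standard
#'   deviation `width / 2`).
#' @param diastolic_width_ms,diastolic_delay_ms,diastolic_rel_amp Diastolic
#'   bump width, delay after the systolic apex, and amplitude relative to
#'   the systolic bump (defaults 220 ms, 280 ms, 0.4).
#' @param amp_drift Depth of the slow sinusoidal multiplicative amplitude
#'   modulation (default 0.2; modulation frequency 0.08 Hz).
#' @param amp_drop_prob Per-beat probability of a sudden amplitude drop
#'   (default 0).
#' @param drop_frac Amplitude multiplier during a drop (default 0.25).
#' @param premature_beat_prob Per-beat probability of inserting a premature
#'   beat at ~55% of the current interval with 60% amplitude (default 0).
#' @param baseline_wander_amp,baseline_wander_freq Baseline wander sinusoid
#'   amplitude (fraction of systolic amplitude) and frequency in Hz
#'   (defaults 0.3, 0.25).
#' @param noise_sd Additive white-noise SD as a fraction of the systolic
#'   amplitude (default 0.02).
#' @param seed RNG seed (default 1); the same seed reproduces the record
#'   exactly.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 367, duration_s = 20, hr_bpm = 76,
                         hr_jitter_frac = 0.03, systolic_width_ms = 150,
                         diastolic_width_ms = 220, diastolic_delay_ms = 280,
                         diastolic_rel_amp = 0.4, amp_drift = 0.2,
                         amp_drop_prob = 0, drop_frac = 0.25,
                         premature_beat_prob = 0, baseline_wander_amp = 0.3,
                         baseline_wander_freq = 0.25, noise_sd = 0.02,
                         seed = 1) {
  check_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(hr_bpm, "hr_bpm", lower = 0, strict_lower = TRUE)
  check_scalar_number(hr_jitter_frac, "hr_jitter_frac", lower = 0, upper = 1)
  for (nm in c("systolic_width_ms", "diastolic_width_ms", "diastolic_delay_ms")) {
    check_scalar_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  for (nm in c("diastolic_rel_amp", "amp_drop_prob", "drop_frac",
               "premature_beat_prob", "baseline_wander_amp", "noise_sd",
               "amp_drift")) {
    check_scalar_number(get(nm), nm, lower = 0)
  }
  if (amp_drop_prob > 1 || premature_beat_prob > 1) {
    validation_error("probabilities must be in [0, 1]")
  }
  if (duration_s * hr_bpm / 60 < 2) {
    validation_error("configuration yields fewer than 2 beats")
  }
  structure(
    list(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
         hr_jitter_frac = hr_jitter_frac,
         systolic_width_ms = systolic_width_ms,
         diastolic_width_ms = diastolic_width_ms,
         diastolic_delay_ms = diastolic_delay_ms,
         diastolic_rel_amp = diastolic_rel_amp, amp_drift = amp_drift,
         amp_drop_prob = amp_drop_prob, drop_frac = drop_frac,
         premature_beat_prob = premature_beat_prob,
         baseline_wander_amp = baseline_wander_amp,
         baseline_wander_freq = baseline_wander_freq, noise_sd = noise_sd,
         seed = seed),
    class = "synth_config"
  )
}

#' Preset synthetic recording conditions
#'
#' `"rest"`: 76 bpm, low noise, no artifacts. `"after_exercise"`: 120 bpm
#' tachycardia with elevated noise, sudden amplitude drops and occasional
#' premature beats, emulating post-exertion heat-stress recordings.
#'
#' @param name `"rest"` or `"after_exercise"`.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("rest", "after_exercise"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    rest = list(hr_bpm = 76, noise_sd = 0.02, amp_drop_prob = 0,
                premature_beat_prob = 0),
    after_exercise = list(hr_bpm = 120, noise_sd = 0.1, amp_drop_prob = 0.05,
                          premature_beat_prob = 0.03)
  )
  dots <- list(...)
  do.call(synth_config, utils::modifyList(base, dots))
}

#' Generate a synthetic PPG record with ground truth
#'
#' Beat times accumulate intervals `60 / hr_bpm * (1 + U(-j, j))`. Each
#' beat contributes a systolic Gaussian and a delayed diastolic Gaussian
#' scaled by a slow sinusoidal amplitude drift and, with probability
#' `amp_drop_prob`, a sudden drop. Premature beats are inserted at ~55% of
#' the running interval with 60% amplitude and are annotated as true beats.
#' Ground-truth indices are the systolic apexes of the pre-noise waveform
#' (the local argmax near each systolic component centre, as a human
#' annotator would mark); additive noise can move the observed maximum by
#' a few further samples, which the evaluation tolerance absorbs.
#'
#' @param config A [synth_config()].
#' @return A `synth_record` list: `record` (a `ppg_record`), `truth`
#'   (a `peak_annotation`), and `beat_log` (a tibble with per-beat time,
#'   amplitude, and premature/dropped flags).
#' @examples
#' s <- synth_ppg(synth_preset("rest", seed = 7))
#' nrow(s$truth)
#' @export
synth_ppg <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) {
    config <- do.call(synth_config, as.list(config))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs)) + 1L
  t <- (seq_len(n) - 1) / fs
  interval <- 60 / config$hr_bpm

  # scheduled beats: first at half an interval, then jittered accumulation
  beat_t <- numeric(0)
  tk <- interval / 2
  while (tk <= config$duration_s - interval / 2 + 1e-9) {
    beat_t <- c(beat_t, tk)
    tk <- tk + interval * (1 + runif(1, -config$hr_jitter_frac,
                                     config$hr_jitter_frac))
  }
  n_sched <- length(beat_t)
  premature <- rep(FALSE, n_sched)

  # premature insertions at ~55% of the local interval, 60% amplitude
  if (config$premature_beat_prob > 0 && n_sched >= 2) {
    ins_t <- numeric(0)
    for (k in seq_len(n_sched - 1)) {
      if (runif(1) < config$premature_beat_prob) {
        ins_t <- c(ins_t, beat_t[k] + 0.55 * (beat_t[k + 1] - beat_t[k]))
      }
    }
    if (length(ins_t) > 0) {
      premature <- c(premature, rep(TRUE, length(ins_t)))
      beat_t <- c(beat_t, ins_t)
      ord <- order(beat_t)
      beat_t <- beat_t[ord]
      premature <- premature[ord]
    }
  }

  drift_phase <- runif(1, 0, 2 * pi)
  amp <- 1 + config$amp_drift * sin(2 * pi * 0.08 * beat_t + drift_phase)
  dropped <- runif(length(beat_t)) < config$amp_drop_prob
  amp[dropped] <- amp[dropped] * config$drop_frac
  amp[premature] <- amp[premature] * 0.6

  # width parameters are the 2-sigma full width: the diastolic bump then
  # rides on the systolic decay (a shoulder with a shallow notch) rather
  # than standing free, matching fingertip PPG morphology
  sys_sd <- config$systolic_width_ms / 2000  # seconds
  dia_sd <- config$diastolic_width_ms / 2000
  dia_delay <- config$diastolic_delay_ms / 1000

  clean <- numeric(n)
  for (k in seq_along(beat_t)) {
    clean <- clean +
      amp[k] * exp(-((t - beat_t[k])^2) / (2 * sys_sd^2)) +
      amp[k] * config$diastolic_rel_amp *
        exp(-((t - beat_t[k] - dia_delay)^2) / (2 * dia_sd^2))
  }
  wander_phase <- runif(1, 0, 2 * pi)
  baseline <- config$baseline_wander_amp *
    sin(2 * pi * config$baseline_wander_freq * t + wander_phase)
  noise <- if (config$noise_sd > 0) rnorm(n, sd = config$noise_sd) else 0
  pre_noise <- clean + baseline
  sig <- pre_noise + noise

  # truth = the systolic apex of the pre-noise waveform: the argmax near the
  # systolic component centre (the overlapping diastolic tail and wander can
  # shift the observed apex by a few samples, as for a human annotator)
  half_win <- as.integer(round(0.25 * config$systolic_width_ms / 1000 * fs))
  centre <- as.integer(round(beat_t * fs)) + 1L
  truth_idx <- vapply(centre, function(c0) {
    lo <- max(1L, c0 - half_win)
    hi <- min(n, c0 + half_win)
    lo + which.max(pre_noise[lo:hi]) - 1L
  }, integer(1))
  keep <- centre >= 1L & centre <= n
  rec <- ppg_record(sig, fs = fs,
                    record_id = sprintf("synth-%d", config$seed),
                    condition = "synthetic")
  structure(
    list(
      record = rec,
      truth = peak_annotation(truth_idx[keep], fs = fs, n_samples = n),
      beat_log = tibble(time_s = beat_t[keep], amplitude = amp[keep],
                        premature = premature[keep], dropped = dropped[keep]),
      config = config
    ),
    class = "synth_record"
  )
}

#' Generate a seeded set of synthetic records
#'
#' Per-record seeds are derived from `seed` by counter, so the set is
#' reproducible and records are mutually independent.
#'
#' @param n Number of records.
#' @param config Base configuration (its `seed` field is overridden).
#' @param seed Integer seed for the set.
#' @return A list of `synth_record`s.
#' @export
synth_dataset <- function(n, config = synth_config(), seed = 1) {
  stopifnot(n >= 1)
  map(seq_len(n), function(k) {
    cfg <- config
    cfg$seed <- seed * 10000 + k
    synth_ppg(cfg)
  })
}
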