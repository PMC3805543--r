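raw_billauer <- billauer_params(use_bandpass = FALSE)

test_that("local-extrema state machine follows the delta rule", {
  rec <- ppg_record(c(0, 1, 0, 1, 0), fs = 10)
  expect_equal(detect_billauer(rec, raw_billauer)$index, c(2L, 4L))
  # a dip smaller than delta does not terminate the peak search
  rec2 <- ppg_record(c(0, 1, 0.95, 1.02, 0), fs = 10)
  expect_equal(detect_billauer(rec2, raw_billauer)$index, 4L)
  # monotone ramp: no descent, no peaks
  ramp <- ppg_record(seq(0, 1, length.out = 50), fs = 10)
  expect_equal(nrow(detect_billauer(ramp, raw_billauer)), 0L)
  expect_error(billauer_params(delta = 0),
               class = "ppgpeaks_validation_error")
})

test_that("local-extrema detection is deliberately not scale invariant", {
  s <- synth_ppg(synth_preset("rest", noise_sd = 0, seed = 9))
  full <- detect_billauer(s$record)
  expect_gt(nrow(full), 0)
  tiny <- ppg_record(s$record$amplitude * 0.01, fs = 367)
  expect_equal(nrow(detect_billauer(tiny)), 0L)
})

test_that("derivative zero crossings sit at sinusoid maxima", {
  s <- sine_record(1.25, duration_s = 8)
  d <- first_difference(s)$amplitude
  neg_cross <- which(d[-length(d)] > 0 & d[-1] <= 0)
  true_max <- which(diff(sign(diff(s$amplitude))) == -2) + 1
  for (m in true_max) {
    expect_lte(min(abs(neg_cross - m)), 1)
  }
})

test_that("first-derivative delineator recovers clean beats", {
  s <- synth_ppg(synth_config(hr_bpm = 75, hr_jitter_frac = 0, noise_sd = 0,
                              seed = 2))
  det <- detect_li(s$record)
  expect_equal(nrow(det), nrow(s$truth))
  ev <- match_peaks(s$truth, det)
  expect_equal(ev$se, 1)
  # flat line: nothing to detect
  flat <- ppg_record(rep(1, 367 * 10), fs = 367)
  expect_equal(nrow(detect_li(flat)), 0L)
  expect_error(detect_li(ppg_record(rnorm(300), fs = 367)),
               class = "ppgpeaks_validation_error")
})

test_that("slope-sum detector honours its refractory period", {
  set.seed(5)
  noise <- ppg_record(rnorm(367 * 12), fs = 367)
  det <- detect_zong(noise)
  refr <- ms_to_samples(300, 367)
  if (nrow(det) > 1) expect_true(all(diff(det$index) >= refr))
  # clean recovery
  s <- synth_ppg(synth_config(hr_bpm = 75, hr_jitter_frac = 0, noise_sd = 0,
                              seed = 3))
  ev <- match_peaks(s$truth, detect_zong(s$record))
  expect_equal(ev$se, 1)
  expect_equal(ev$ppv, 1)
  # degenerate all-zero record
  zero <- ppg_record(rep(0, 367 * 10), fs = 367)
  expect_equal(nrow(detect_zong(zero)), 0L)
  expect_error(detect_zong(ppg_record(rnorm(100), fs = 367)),
               class = "ppgpeaks_validation_error")
})

test_that("block generation finds maximal runs above threshold", {
  blocks <- generate_blocks(c(0, 1, 1, 0, 1), rep(0.5, 5))
  expect_equal(blocks$onset, c(2L, 5L))
  expect_equal(blocks$offset, c(4L, 6L))
  expect_equal(nrow(generate_blocks(rep(0, 5), rep(0.5, 5))), 0L)
  all_above <- generate_blocks(rep(1, 7), rep(0, 7))
  expect_equal(all_above$onset, 1L)
  expect_equal(all_above$offset, 8L)
  expect_error(generate_blocks(1:3, 1:4), class = "ppgpeaks_validation_error")
})

test_that("block rejection keeps widths at or above the duration threshold", {
  b <- tibble::tibble(onset = c(1L, 100L, 200L),
                      offset = c(41L, 141L, 245L))  # widths 40, 41, 45
  kept <- reject_blocks(b, 41)
  expect_equal(kept$offset - kept$onset, c(41L, 45L))
  expect_equal(nrow(reject_blocks(b[0, ], 41)), 0L)
  expect_equal(nrow(reject_blocks(b, 1)), 3L)
  # output size is monotone non-increasing in the threshold
  sizes <- vapply(c(1, 40, 41, 44, 45, 46), function(th) {
    nrow(reject_blocks(b, th))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("dual moving-average detector recovers clean beats exactly", {
  s <- synth_ppg(synth_preset("rest", noise_sd = 0, seed = 1))
  ev <- match_peaks(s$truth, detect_elgendi(s$record))
  expect_equal(ev$se, 1)
  expect_equal(ev$ppv, 1)
  # all-zero record: equal averages never strictly exceed the threshold
  zero <- ppg_record(rep(0, 367 * 10), fs = 367)
  expect_equal(nrow(detect_elgendi(zero)), 0L)
  expect_error(elgendi_params(w1_ms = 700, w2_ms = 600),
               class = "ppgpeaks_validation_error")
})

test_that("an isolated systolic pulse yields exactly one block at its apex", {
  fs <- 367
  t <- seq(0, 10, by = 1 / fs)
  apex_t <- 5
  sd_s <- 0.150 / 4  # 150 ms wide bump over silence
  pulse <- exp(-((t - apex_t)^2) / (2 * sd_s^2))
  rec <- ppg_record(pulse, fs = fs)
  det <- detect_elgendi(rec)
  expect_equal(nrow(det), 1L)
  expect_lte(abs(det$index - (round(apex_t * fs) + 1)), 2)
})

test_that("dual moving-average detection is invariant to positive scaling", {
  for (seed in 1:5) {
    s <- synth_ppg(synth_preset("after_exercise", seed = seed))
    base <- detect_elgendi(s$record)$index
    scaled <- ppg_record(s$record$amplitude * 1000, fs = 367)
    expect_identical(detect_elgendi(scaled)$index, base)
  }
})

test_that("block count is monotone non-increasing in the offset beta", {
  s <- synth_ppg(synth_preset("after_exercise", seed = 8))
  z <- s$record |>
    butter_zero_phase("bandpass", 0.5, 8) |>
    clip_above_zero() |>
    square_signal()
  w1 <- ma_window_samples(111, 367)
  w2 <- ma_window_samples(667, 367)
  ma_peak <- moving_average(z, 111)$amplitude
  ma_beat <- moving_average(z, 667)$amplitude
  counts <- vapply(c(0, 0.01, 0.02, 0.05, 0.1, 0.5), function(beta) {
    nrow(generate_blocks(ma_peak, ma_beat + beta * mean(z$amplitude)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every detector returns strictly increasing in-bound indices", {
  s <- synth_ppg(synth_preset("after_exercise", noise_sd = 0.3,
                              amp_drop_prob = 0.3, seed = 13))
  n <- nrow(s$record)
  for (m in c("elgendi", "billauer", "li", "zong")) {
    idx <- detect_peaks(s$record, m)$index
    expect_true(all(diff(idx) > 0), info = m)
    expect_true(all(idx >= 1 & idx <= n), info = m)
  }
})
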