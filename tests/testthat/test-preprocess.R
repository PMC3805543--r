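test_that("millisecond-to-sample conversions follow the rounding rules", {
  expect_identical(ms_to_samples(128, 367), 47L)
  expect_identical(ma_window_samples(111, 367), 41L)
  expect_identical(ma_window_samples(667, 367), 245L)
  # nearest-odd on an even count resolves upward
  expect_identical(ma_window_samples(40 / 367 * 1000, 367), 41L)
})

test_that("bandpass removes DC and passes the pulse band without lag", {
  fs <- 367
  const <- ppg_record(rep(3.7, 20 * fs), fs = fs)
  out <- butter_zero_phase(const, "bandpass", 0.5, 8)
  expect_lt(max(abs(out$amplitude)), 1e-8 * 3.7)

  s4 <- sine_record(4)
  y4 <- butter_zero_phase(s4, "bandpass", 0.5, 8)
  core <- 1000:6000
  expect_lt(abs(max(abs(y4$amplitude[core])) - 1), 0.05)
  # zero phase: peak positions coincide
  p_in <- 1000 + which.max(s4$amplitude[1000:2000]) - 1
  p_out <- 1000 + which.max(y4$amplitude[1000:2000]) - 1
  expect_equal(p_in, p_out)
})

test_that("stopband attenuation matches the designed frequency response", {
  fs <- 367
  bf <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  h <- signal::freqz(bf, Fs = fs)
  # two passes square the magnitude response
  gain40 <- abs(h$h[which.min(abs(h$f - 40))])^2
  s40 <- sine_record(40)
  y40 <- butter_zero_phase(s40, "bandpass", 0.5, 8)
  measured <- max(abs(y40$amplitude[1000:6000]))
  expect_lt(measured, 0.15)
  expect_equal(measured, gain40, tolerance = 0.1)
})

test_that("zero-phase filtering is symmetric under time reversal", {
  fs <- 367
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 1.25 * t) + 0.4 * sin(2 * pi * 2.5 * t + 1) +
    0.3 * sin(2 * pi * 0.25 * t)
  rec <- ppg_record(x, fs = fs)
  rev_rec <- ppg_record(rev(x), fs = fs)
  y <- butter_zero_phase(rec, "bandpass", 0.5, 8)$amplitude
  yr <- rev(butter_zero_phase(rev_rec, "bandpass", 0.5, 8)$amplitude)
  expect_lt(max(abs(y - yr)) / max(abs(y)), 1e-5)
})

test_that("filter validation rejects bad corners and short records", {
  rec <- sine_record(4)
  expect_error(butter_zero_phase(rec, "bandpass", 0.5, 200),
               class = "ppgpeaks_validation_error")
  expect_error(butter_zero_phase(rec, "bandpass", 8, 0.5),
               class = "ppgpeaks_validation_error")
  short <- ppg_record(rnorm(500), fs = 367)
  expect_error(butter_zero_phase(short, "bandpass", 0.5, 8),
               class = "ppgpeaks_validation_error")
})

test_that("clipping and squaring follow their definitions", {
  rec <- ppg_record(c(-2, 3, 0), fs = 10)
  expect_equal(clip_above_zero(rec)$amplitude, c(0, 3, 0))
  expect_equal(clip_above_zero(ppg_record(c(-1, -5, -0.1), fs = 10))$amplitude,
               c(0, 0, 0))
  nn <- ppg_record(c(0.5, 2, 0), fs = 10)
  expect_equal(clip_above_zero(nn)$amplitude, nn$amplitude)
  expect_equal(square_signal(nn)$amplitude, c(0.25, 4, 0))
  # squaring preserves the argmax of a non-negative signal
  set.seed(1)
  v <- abs(rnorm(50))
  sq <- square_signal(ppg_record(v, fs = 10))
  expect_equal(which.max(sq$amplitude), which.max(v))
})

test_that("moving average matches the brute-force oracle and is linear", {
  fs <- 367
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:1000, 1)
    w <- 2 * sample(0:min(49, (n - 1) %/% 2), 1) + 1
    v <- rnorm(n)
    got <- moving_average(ppg_record(v, fs = fs), w * 1000 / fs)$amplitude
    expect_equal(got, brute_moving_average(v, w), tolerance = 1e-12)
  }
  # linearity
  x <- rnorm(300); y <- rnorm(300)
  ma <- function(v) moving_average(ppg_record(v, fs = fs), 111)$amplitude
  expect_equal(ma(2 * x + 3 * y), 2 * ma(x) + 3 * ma(y), tolerance = 1e-12)
  # constant in, constant out
  expect_equal(ma(rep(4.2, 300)), rep(4.2, 300), tolerance = 1e-12)
  expect_error(moving_average(ppg_record(rnorm(10), fs = fs), 1000),
               class = "ppgpeaks_validation_error")
})

test_that("first difference is length-preserving with a zero head", {
  rec <- ppg_record(c(0, 1, 3, 2), fs = 10)
  expect_equal(first_difference(rec)$amplitude, c(0, 1, 2, -1))
  inc <- ppg_record(cumsum(abs(rnorm(50))), fs = 10)
  expect_true(all(first_difference(inc)$amplitude >= 0))
  expect_equal(first_difference(ppg_record(rep(2, 10), fs = 10))$amplitude,
               rep(0, 10))
  expect_error(first_difference(ppg_record(1, fs = 10)),
               class = "ppgpeaks_validation_error")
})

test_that("slope sum matches its closed forms and shift invariance", {
  fs <- 367
  # monotone non-increasing input gives identically zero SSF
  dec <- ppg_record(seq(10, 1, length.out = 400), fs = fs)
  expect_equal(slope_sum(dec)$amplitude, rep(0, 400))
  # ramp of slope s: interior SSF equals w * s
  w <- ms_to_samples(128, fs)
  s <- 0.37
  ramp <- ppg_record(s * (1:400), fs = fs)
  ssf <- slope_sum(ramp)$amplitude
  expect_equal(ssf[(w + 1):400], rep(w * s, 400 - w), tolerance = 1e-10)
  # truncated leading edge matches the brute-force oracle
  set.seed(3)
  v <- rnorm(300)
  expect_equal(slope_sum(ppg_record(v, fs = fs))$amplitude,
               brute_slope_sum(v, w), tolerance = 1e-10)
  # invariant to adding a constant
  expect_equal(slope_sum(ppg_record(v + 100, fs = fs))$amplitude,
               slope_sum(ppg_record(v, fs = fs))$amplitude, tolerance = 1e-9)
  expect_error(slope_sum(ppg_record(rnorm(40), fs = fs)),
               class = "ppgpeaks_validation_error")
})
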