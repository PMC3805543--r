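test_that("matching applies the inclusive time tolerance", {
  # 10 samples at 367 Hz is 27.2 ms, inside +/-50 ms
  ev <- match_peaks(peak_annotation(100, fs = 367),
                    peak_annotation(110, fs = 367), 50)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(1, 0, 0))
  expect_equal(ev$se, 1)
  expect_equal(ev$ppv, 1)

  ev2 <- suppressWarnings(
    match_peaks(peak_annotation(100, fs = 367),
                peak_annotation(integer(0), fs = 367), 50))
  expect_equal(c(ev2$tp, ev2$fp, ev2$fn), c(0, 0, 1))
  expect_equal(ev2$se, 0)

  ev3 <- match_peaks(peak_annotation(c(100, 300), fs = 367),
                     peak_annotation(c(101, 299, 500), fs = 367), 50)
  expect_equal(c(ev3$tp, ev3$fp, ev3$fn), c(2, 1, 0))
  expect_equal(ev3$se, 1)
  expect_equal(ev3$ppv, 2 / 3)

  # boundary: exactly the tolerance is a match
  tol_samples <- floor(50 * 367 / 1000)
  ev4 <- match_peaks(peak_annotation(1000, fs = 367),
                     peak_annotation(1000 + tol_samples, fs = 367), 50)
  expect_equal(ev4$tp, 1)
  expect_error(match_peaks(peak_annotation(1, fs = 367),
                           peak_annotation(1, fs = 367), -1),
               class = "ppgpeaks_validation_error")
})

test_that("derived statistics follow their definitions", {
  ev <- match_peaks(
    peak_annotation(seq(100, by = 100, length.out = 100), fs = 367),
    peak_annotation(seq(100, by = 100, length.out = 99), fs = 367), 50)
  expect_equal(c(ev$tp, ev$fn, ev$fp), c(99, 1, 0))
  expect_equal(ev$se, 0.99)
  expect_equal(ev$overall, (ev$se + ev$ppv) / 2)
  td <- tidy(ev)
  expect_equal(td$tp, 99)
  expect_equal(td$overall, ev$overall)
})

test_that("greedy matching equals optimal matching for separated beats", {
  # truths separated by more than twice the tolerance: each detection can
  # match at most one truth, where greedy is provably optimal
  fs <- 367
  tol_ms <- 50
  tol_samples <- tol_ms * fs / 1000
  set.seed(42)
  for (rep in 1:60) {
    n_t <- sample(0:8, 1)
    ti <- sort(sample(seq(50, 8000, by = ceiling(2 * tol_samples) + 5), n_t))
    di <- unlist(lapply(ti, function(x) {
      if (runif(1) < 0.8) x + sample(-25:25, 1) else integer(0)
    }))
    di <- sort(unique(c(di, sample(8000, sample(0:3, 1)))))
    ev <- suppressWarnings(match_peaks(
      peak_annotation(ti, fs = fs), peak_annotation(di, fs = fs), tol_ms))
    expect_equal(ev$tp, optimal_match_count(ti, di, tol_samples))
    expect_equal(ev$fp, length(di) - ev$tp)
    expect_equal(ev$fn, length(ti) - ev$tp)
  }
})

test_that("greedy matching never exceeds optimal on arbitrary instances", {
  fs <- 367
  tol_samples <- 50 * 367 / 1000
  set.seed(17)
  for (rep in 1:40) {
    ti <- sort(sample(500, sample(1:8, 1)))
    di <- sort(sample(500, sample(1:8, 1)))
    ev <- suppressWarnings(match_peaks(
      peak_annotation(ti, fs = fs), peak_annotation(di, fs = fs), 50))
    expect_lte(ev$tp, optimal_match_count(ti, di, tol_samples))
  }
})

test_that("matching is symmetric and monotone in the tolerance", {
  set.seed(6)
  ti <- sort(sample(5000, 20))
  di <- sort(sample(5000, 24))
  a <- suppressWarnings(match_peaks(peak_annotation(ti, fs = 367),
                                    peak_annotation(di, fs = 367), 50))
  b <- suppressWarnings(match_peaks(peak_annotation(di, fs = 367),
                                    peak_annotation(ti, fs = 367), 50))
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)

  tols <- c(0, 10, 25, 50, 100, 200)
  tps <- vapply(tols, function(tol) {
    suppressWarnings(match_peaks(peak_annotation(ti, fs = 367),
                                 peak_annotation(di, fs = 367), tol))$tp
  }, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("dataset evaluation pools counts across records", {
  mk <- function(tp, fp, fn) {
    truth <- peak_annotation(seq(100, by = 200, length.out = tp + fn),
                             fs = 367)
    hits <- truth$index[seq_len(tp)]
    extras <- seq(10000, by = 200, length.out = fp)
    list(truth = truth,
         detected = peak_annotation(c(hits, extras), fs = 367))
  }
  pooled <- evaluate_dataset(list(mk(10, 1, 0), mk(10, 1, 0)), 50)
  expect_equal(c(pooled$tp, pooled$fp, pooled$fn), c(20, 2, 0))
  expect_equal(pooled$ppv, 20 / 22)

  single <- mk(5, 2, 3)
  expect_equal(tidy(evaluate_dataset(list(single), 50)),
               tidy(match_peaks(single$truth, single$detected, 50)))
  expect_error(evaluate_dataset(list(), 50),
               class = "ppgpeaks_validation_error")
})
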