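# Independent oracles and shared fixtures.

# brute-force centered moving average: per-index loop with truncated edges
brute_moving_average <- function(v, w) {
  h <- (w - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# brute-force slope sum: per-index double loop
brute_slope_sum <- function(v, w) {
  n <- length(v)
  d <- c(0, diff(v))
  vapply(seq_len(n), function(i) {
    sum(pmax(d[max(2, i - w + 1):i], 0)) * (i >= 2)
  }, numeric(1))
}

# exhaustive maximum bipartite matching of truths to detections within a
# sample tolerance (branch and bound over truth indices)
optimal_match_count <- function(ti, di, tol_samples) {
  n_t <- length(ti)
  n_d <- length(di)
  if (n_t == 0 || n_d == 0) return(0L)
  best <- 0L
  used <- rep(FALSE, n_d)
  rec <- function(k, count) {
    if (count + (n_t - k + 1L) <= best) return()
    if (k > n_t) {
      best <<- max(best, count)
      return()
    }
    for (j in seq_len(n_d)) {
      if (!used[j] && abs(ti[k] - di[j]) <= tol_samples) {
        used[j] <<- TRUE
        rec(k + 1L, count + 1L)
        used[j] <<- FALSE
      }
    }
    rec(k + 1L, count)
  }
  rec(1L, 0L)
  best
}

sine_record <- function(freq_hz, fs = 367, duration_s = 20, amp = 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  ppg_record(amp * sin(2 * pi * freq_hz * t), fs = fs)
}

# cached datasets shared across test files (generation is deterministic)
.fixture_cache <- new.env(parent = emptyenv())

clean_rest_set <- function(n = 20, seed = 11) {
  key <- sprintf("clean_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- synth_dataset(
      n, synth_preset("rest", noise_sd = 0), seed = seed)
  }
  .fixture_cache[[key]]
}

degraded_set <- function(n = 50, seed = 12) {
  key <- sprintf("degraded_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- synth_dataset(
      n, synth_preset("after_exercise", amp_drop_prob = 0.3, noise_sd = 0.3),
      seed = seed)
  }
  .fixture_cache[[key]]
}

detections_for <- function(set, method, params = NULL) {
  lapply(set, function(s) {
    list(truth = s$truth, detected = detect_peaks(s$record, method, params))
  })
}
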