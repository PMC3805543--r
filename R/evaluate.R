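# Beat-detection scoring: one-to-one matching of detections to annotations
# within a time tolerance, and the derived sensitivity / positive
# predictivity statistics.

new_ppg_eval <- function(tp, fp, fn, tolerance_ms) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  se <- if (tp + fn > 0) tp / (tp + fn) else 1
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 1
  if (tp + fn == 0 || tp + fp == 0) {
    warn("no annotations or no detections: vacuous SE/+P reported as 1")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, se = se, ppv = ppv,
         overall = (se + ppv) / 2, tolerance_ms = tolerance_ms),
    class = "ppg_eval"
  )
}

#' Match detected peaks against an annotation
#'
#' Pairs detections with annotated peaks one-to-one, greedily in order of
#' increasing absolute time difference; a pair within `tolerance_ms`
#' (inclusive) is a true positive. Unmatched annotations are false
#' negatives, unmatched detections false positives. For well-separated
#' beats (beat spacing much larger than the tolerance) greedy matching is
#' optimal.
#'
#' @param truth A `peak_annotation` of ground-truth systolic peaks.
#' @param detected A `peak_annotation` of detected peaks (same `fs`).
#' @param tolerance_ms Match tolerance in milliseconds (default 50, applied
#'   as a closed interval).
#' @param fs Sampling frequency; defaults to the annotations' own.
#' @return A `ppg_eval` object with counts `tp`, `fp`, `fn` and rates `se`
#'   (sensitivity), `ppv` (positive predictivity) and `overall`
#'   (their mean). Use [tidy()] for a one-row tibble.
#' @examples
#' truth <- peak_annotation(c(100, 300), fs = 367)
#' det <- peak_annotation(c(101, 299, 500), fs = 367)
#' match_peaks(truth, det)
#' @export
match_peaks <- function(truth, detected, tolerance_ms = 50, fs = NULL) {
  if (tolerance_ms < 0) validation_error("tolerance_ms must be >= 0")
  fs <- fs %||% ppg_fs(truth)
  ti <- peak_indices(truth)
  di <- peak_indices(detected)
  tol_samples <- tolerance_ms * fs / 1000
  if (length(ti) == 0 || length(di) == 0) {
    return(new_ppg_eval(tp = 0, fp = length(di), fn = length(ti),
                        tolerance_ms = tolerance_ms))
  }
  # candidate pairs within tolerance, nearest first; ties resolve by truth
  # then detection order for determinism
  pairs <- tidyr::expand_grid(t = seq_along(ti), d = seq_along(di))
  pairs$dist <- abs(ti[pairs$t] - di[pairs$d])
  pairs <- pairs[pairs$dist <= tol_samples, , drop = FALSE]
  pairs <- pairs[order(pairs$dist, pairs$t, pairs$d), , drop = FALSE]
  t_used <- rep(FALSE, length(ti))
  d_used <- rep(FALSE, length(di))
  tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    t <- pairs$t[r]; d <- pairs$d[r]
    if (!t_used[t] && !d_used[d]) {
      t_used[t] <- TRUE
      d_used[d] <- TRUE
      tp <- tp + 1L
    }
  }
  new_ppg_eval(tp = tp, fp = sum(!d_used), fn = sum(!t_used),
               tolerance_ms = tolerance_ms)
}

#' Pool evaluation over a dataset
#'
#' Pools TP/FP/FN counts across records (micro-averaging), then derives
#' SE, +P and overall accuracy from the pooled counts.
#'
#' @param pairs A list whose elements each contain `truth` and `detected`
#'   peak annotations (extra elements such as `record` are ignored).
#' @param tolerance_ms Match tolerance in milliseconds.
#' @return A pooled `ppg_eval`.
#' @export
evaluate_dataset <- function(pairs, tolerance_ms = 50) {
  if (length(pairs) == 0) validation_error("empty dataset")
  evals <- map(pairs, function(p) {
    suppressWarnings(match_peaks(p$truth, p$detected, tolerance_ms))
  })
  new_ppg_eval(
    tp = sum(map_dbl(evals, "tp")),
    fp = sum(map_dbl(evals, "fp")),
    fn = sum(map_dbl(evals, "fn")),
    tolerance_ms = tolerance_ms
  )
}

#' @export
print.ppg_eval <- function(x, ...) {
  cat(sprintf(
    "Peak-detection evaluation (tolerance %g ms)\n  TP %d  FP %d  FN %d\n  SE %.2f%%  +P %.2f%%  overall %.2f%%\n",
    x$tolerance_ms, x$tp, x$fp, x$fn,
    100 * x$se, 100 * x$ppv, 100 * x$overall))
  invisible(x)
}

#' @rdname match_peaks
#' @param x A `ppg_eval` object.
#' @param ... Unused.
#' @export
tidy.ppg_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, se = x$se, ppv = x$ppv,
         overall = x$overall, tolerance_ms = x$tolerance_ms)
}

#' @rdname match_peaks
#' @export
glance.ppg_eval <- function(x, ...) tidy(x)
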