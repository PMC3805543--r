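# Brute-force grid search over the dual moving-average detector parameters:
# every valid (f1, f2, W1, W2, beta) combination is scored on a training set
# by pooled sensitivity / positive predictivity, and the full table is
# returned sorted by overall accuracy.

#' Parameter grid for the brute-force search
#'
#' The default grid reconstructs the published search ranges: low corner
#' 0.5-1 Hz, high corner 7-15 Hz, systolic window 54-111 ms, beat window
#' 545-694 ms, offset 0-10% of the mean squared signal. Any `(f1, f2)` pair
#' with `f1 >= f2` is skipped and counted as invalid.
#'
#' @param f1_values,f2_values Bandpass corners to try, in Hz.
#' @param w1_values,w2_values Moving-average windows to try, in ms.
#' @param beta_values Offsets to try, in percent (2 means beta = 0.02).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(f1_values = c(0.5, 1),
                      f2_values = 7:15,
                      w1_values = c(54, 69, 83, 97, 111),
                      w2_values = c(545, 575, 605, 635, 665, 694),
                      beta_values = 0:10) {
  for (nm in c("f1_values", "f2_values", "w1_values", "w2_values",
               "beta_values")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) == 0) {
      validation_error(sprintf("`%s` must be a nonempty numeric vector", nm))
    }
  }
  structure(list(f1_values = f1_values, f2_values = f2_values,
                 w1_values = w1_values, w2_values = w2_values,
                 beta_values = beta_values),
            class = "grid_spec")
}

#' Brute-force parameter optimisation of the dual moving-average detector
#'
#' Runs [detect_elgendi()] with every valid grid combination on every
#' record, pools TP/FP/FN across records, and returns all rows sorted by
#' overall accuracy (descending). Ties break by higher sensitivity, then
#' lower `w1_ms`, lower `beta`, lower `f2` -- a deterministic order. The
#' whole pipeline is deterministic, so re-running with identical inputs
#' reproduces the table exactly.
#'
#' @param dataset A list whose elements contain `record` (a `ppg_record`)
#'   and `truth` (a `peak_annotation`); [synth_dataset()] output works
#'   directly.
#' @param grid A [grid_spec()].
#' @param tolerance_ms Match tolerance in milliseconds (default 50).
#' @return A `ppg_grid` object: `rows` (a tibble with one row per evaluated
#'   combination: `f1, f2, w1_ms, w2_ms, beta_pct, tp, fp, fn, se, ppv,
#'   overall`) and `n_iterations` (number of valid combinations). `tidy()`
#'   returns the rows, `glance()` the top row.
#' @export
grid_search <- function(dataset, grid = grid_spec(), tolerance_ms = 50) {
  if (length(dataset) == 0) validation_error("empty dataset")
  if (!inherits(grid, "grid_spec")) grid <- do.call(grid_spec, as.list(grid))
  combos <- tidyr::expand_grid(
    f1 = grid$f1_values, f2 = grid$f2_values,
    w1_ms = grid$w1_values, w2_ms = grid$w2_values,
    beta_pct = grid$beta_values
  )
  combos <- combos[combos$f1 < combos$f2, , drop = FALSE]
  if (nrow(combos) == 0) validation_error("grid contains no valid combination")

  # cache: the filtered/squared signal depends only on (f1, f2)
  score_band <- function(f1, f2, sub) {
    z <- map(dataset, function(d) {
      d$record |>
        butter_zero_phase("bandpass", f1, f2) |>
        clip_above_zero() |>
        square_signal()
    })
    fs <- ppg_fs(dataset[[1]]$record)
    pmap(sub, function(w1_ms, w2_ms, beta_pct, ...) {
      w1 <- ma_window_samples(w1_ms, fs)
      w2 <- ma_window_samples(w2_ms, fs)
      evals <- map2(z, dataset, function(zz, d) {
        ma_peak <- moving_average_num(zz$amplitude, w1)
        ma_beat <- moving_average_num(zz$amplitude, w2)
        thr1 <- ma_beat + (beta_pct / 100) * mean(zz$amplitude)
        blocks <- reject_blocks(generate_blocks(ma_peak, thr1), w1)
        peaks <- purrr::map2_int(blocks$onset, blocks$offset, function(on, off) {
          on + which.max(zz$amplitude[on:(off - 1L)]) - 1L
        })
        det <- peak_annotation(peaks, fs = fs, n_samples = nrow(zz))
        suppressWarnings(match_peaks(d$truth, det, tolerance_ms))
      })
      tibble(tp = sum(map_dbl(evals, "tp")), fp = sum(map_dbl(evals, "fp")),
             fn = sum(map_dbl(evals, "fn")))
    }) |> list_rbind()
  }

  bands <- dplyr::distinct(combos[, c("f1", "f2")])
  rows <- map(seq_len(nrow(bands)), function(i) {
    sub <- combos[combos$f1 == bands$f1[i] & combos$f2 == bands$f2[i], ,
                  drop = FALSE]
    dplyr::bind_cols(sub, score_band(bands$f1[i], bands$f2[i], sub))
  }) |> list_rbind()

  rows$se <- ifelse(rows$tp + rows$fn > 0, rows$tp / (rows$tp + rows$fn), 1)
  rows$ppv <- ifelse(rows$tp + rows$fp > 0, rows$tp / (rows$tp + rows$fp), 1)
  rows$overall <- (rows$se + rows$ppv) / 2
  rows <- rows[order(-rows$overall, -rows$se, rows$w1_ms, rows$beta_pct,
                     rows$f2, rows$f1, rows$w2_ms), , drop = FALSE]
  structure(
    list(rows = as_tibble(rows), n_iterations = nrow(rows),
         tolerance_ms = tolerance_ms),
    class = "ppg_grid"
  )
}

#' Best parameter bundle from a grid search
#' @param x A `ppg_grid`.
#' @return The top row's parameters as an [elgendi_params()].
#' @export
best_params <- function(x) {
  stopifnot(inherits(x, "ppg_grid"))
  top <- x$rows[1, ]
  elgendi_params(f1 = top$f1, f2 = top$f2, w1_ms = top$w1_ms,
                 w2_ms = top$w2_ms, beta = top$beta_pct / 100)
}

#' @export
print.ppg_grid <- function(x, ...) {
  cat(sprintf("Brute-force grid search: %d combinations (tolerance %g ms)\n",
              x$n_iterations, x$tolerance_ms))
  print(head(x$rows, 10))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `ppg_grid` object.
#' @param ... Unused.
#' @export
tidy.ppg_grid <- function(x, ...) x$rows

#' @rdname grid_search
#' @export
glance.ppg_grid <- function(x, ...) {
  dplyr::bind_cols(x$rows[1, ], tibble(n_iterations = x$n_iterations))
}
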