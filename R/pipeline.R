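# End-to-end protocol: write a ground-truthed fixture set, optimise the
# dual moving-average detector on the rest-condition records only, freeze
# the best parameters, and score all four detectors on every condition.

#' Write a synthetic fixture set with manifest
#'
#' Generates `n_per_condition` records for the rest condition and for each
#' of three after-exercise conditions, writes record CSVs and annotation
#' TXTs, and a manifest CSV (`record_path, annotation_path, condition`)
#' consumable by [run_pipeline()].
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_condition Records per condition (default 5).
#' @param seed Integer seed.
#' @param fs Sampling frequency in Hz.
#' @return Path to the manifest CSV, invisibly.
#' @export
synth_fixture_set <- function(out_dir, n_per_condition = 5, seed = 1,
                              fs = 367) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- c("rest", "after_exercise_1", "after_exercise_2",
                  "after_exercise_3")
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    preset <- if (cond == "rest") "rest" else "after_exercise"
    recs <- synth_dataset(n_per_condition,
                          synth_preset(preset, fs = fs),
                          seed = seed * 10 + ci)
    for (k in seq_along(recs)) {
      rp <- file.path(out_dir, sprintf("%s_%02d.csv", cond, k))
      ap <- file.path(out_dir, sprintf("%s_%02d.ann.txt", cond, k))
      write_ppg_record(recs[[k]]$record, rp)
      write_peak_annotation(recs[[k]]$truth, ap)
      rows[[length(rows) + 1]] <- tibble(record_path = rp,
                                         annotation_path = ap,
                                         condition = cond)
    }
  }
  manifest <- list_rbind(rows)
  mp <- file.path(out_dir, "manifest.csv")
  write.table(manifest, mp, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a dataset manifest
#' @param path Manifest CSV with columns `record_path`, `annotation_path`,
#'   `condition`; relative paths resolve against the manifest's directory.
#' @param fs Sampling frequency of the records, in Hz.
#' @return A list of `(record, truth, condition)` entries.
#' @export
read_manifest <- function(path, fs = 367) {
  if (!file.exists(path)) {
    abort(sprintf("manifest not found: %s", path), class = "ppgpeaks_io_error")
  }
  m <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("record_path", "annotation_path", "condition")
  if (!all(need %in% names(m))) {
    validation_error("manifest must have columns record_path, annotation_path, condition")
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  map(seq_len(nrow(m)), function(i) {
    cond <- m$condition[i]
    list(
      record = read_ppg_record(resolve(m$record_path[i]), fs = fs,
                               condition = if (cond %in% ppg_conditions) cond else "synthetic"),
      truth = read_peak_annotation(resolve(m$annotation_path[i]), fs = fs),
      condition = cond
    )
  })
}

#' Train-on-rest / test-on-exercise evaluation pipeline
#'
#' Optimises the dual moving-average detector by brute force on the
#' manifest's rest-condition records only, freezes the best parameters, and
#' evaluates all four detectors on every condition without further
#' adjustment. Writes two CSVs to `out_dir`: `grid.csv` (the full sorted
#' search table) and `report.csv` (method x condition with FP, FN, SE(%),
#' +P(%), overall(%), two decimals), plus `params.json`-style provenance in
#' `params.txt`. Deterministic: identical inputs give byte-identical
#' outputs.
#'
#' @param manifest Path to a manifest CSV (see [read_manifest()]).
#' @param grid A [grid_spec()] for the training search.
#' @param tolerance_ms Match tolerance in milliseconds.
#' @param out_dir Output directory.
#' @param fs Sampling frequency in Hz.
#' @return A list with `best` (frozen [elgendi_params()]), `grid`
#'   (`ppg_grid`), and `report` (tibble), invisibly.
#' @export
run_pipeline <- function(manifest, grid = grid_spec(), tolerance_ms = 50,
                         out_dir = dirname(manifest), fs = 367) {
  entries <- read_manifest(manifest, fs = fs)
  conditions <- map_chr(entries, "condition")
  rest <- entries[conditions == "rest"]
  if (length(rest) == 0) validation_error("manifest has no rest records")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message(sprintf("pipeline: optimising on %d rest records", length(rest)))
  gs <- grid_search(rest, grid, tolerance_ms)
  best <- best_params(gs)
  message(sprintf("pipeline: frozen parameters f=%g-%g Hz W1=%g ms W2=%g ms beta=%g",
                  best$f1, best$f2, best$w1_ms, best$w2_ms, best$beta))

  methods <- c("billauer", "li", "zong", "elgendi")
  report <- list()
  for (cond in unique(conditions)) {
    sub <- entries[conditions == cond]
    for (m in methods) {
      params <- if (m == "elgendi") best else NULL
      pairs <- map(sub, function(e) {
        list(truth = e$truth,
             detected = detect_peaks(e$record, m, params))
      })
      ev <- evaluate_dataset(pairs, tolerance_ms)
      report[[length(report) + 1]] <- tibble(
        condition = cond, method = m, tp = ev$tp, fp = ev$fp, fn = ev$fn,
        se_pct = sprintf("%.2f", 100 * ev$se),
        ppv_pct = sprintf("%.2f", 100 * ev$ppv),
        overall_pct = sprintf("%.2f", 100 * ev$overall)
      )
    }
  }
  report <- list_rbind(report)

  grid_out <- tidy(gs)
  grid_out$se <- sprintf("%.2f", 100 * grid_out$se)
  grid_out$ppv <- sprintf("%.2f", 100 * grid_out$ppv)
  grid_out$overall <- sprintf("%.2f", 100 * grid_out$overall)
  write.table(grid_out, file.path(out_dir, "grid.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(report, file.path(out_dir, "report.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  writeLines(
    c(sprintf("tolerance_ms=%g", tolerance_ms),
      sprintf("fs=%g", fs),
      sprintf("f1=%g", best$f1), sprintf("f2=%g", best$f2),
      sprintf("w1_ms=%g", best$w1_ms), sprintf("w2_ms=%g", best$w2_ms),
      sprintf("beta=%g", best$beta)),
    file.path(out_dir, "params.txt")
  )
  invisible(list(best = best, grid = gs, report = report))
}
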