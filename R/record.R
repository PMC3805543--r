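# Core record and annotation containers. Both are tibbles carrying their
# sampling frequency and provenance as attributes, so they pipe through dplyr
# verbs while staying self-describing.

ppg_conditions <- c("rest", "after_exercise_1", "after_exercise_2",
                    "after_exercise_3", "synthetic")

#' Construct a PPG record
#'
#' A `ppg_record` is a tibble with columns `time` (seconds) and `amplitude`
#' (arbitrary units), plus attributes `fs` (sampling frequency, Hz),
#' `record_id` and `condition`. All downstream detectors and preprocessing
#' stages take and return this shape.
#'
#' @param amplitude Numeric vector of signal samples (finite, length >= 1).
#' @param fs Sampling frequency in Hz (> 0). The study device samples at
#'   367 Hz, the package default.
#' @param record_id Identifier string.
#' @param condition One of `"rest"`, `"after_exercise_1"`, `"after_exercise_2"`,
#'   `"after_exercise_3"`, `"synthetic"`.
#' @param stage Processing stage label (e.g. `"raw"`, `"filtered"`, `"squared"`).
#' @return A `ppg_record` tibble.
#' @examples
#' rec <- ppg_record(sin(2 * pi * 1.2 * seq(0, 5, by = 1 / 367)), fs = 367)
#' ppg_fs(rec)
#' @export
ppg_record <- function(amplitude, fs = 367, record_id = "rec",
                       condition = "synthetic", stage = "raw") {
  if (!is.numeric(amplitude) || length(amplitude) < 1L) {
    validation_error("`amplitude` must be a numeric vector of length >= 1")
  }
  if (!all(is.finite(amplitude))) {
    validation_error("`amplitude` must contain only finite values")
  }
  check_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  condition <- match.arg(condition, ppg_conditions)
  out <- tibble(
    time = (seq_along(amplitude) - 1) / fs,
    amplitude = as.numeric(amplitude)
  )
  structure(out,
    class = c("ppg_record", class(out)),
    fs = fs, record_id = record_id, condition = condition, stage = stage
  )
}

# rebuild a record with new amplitudes but the same metadata
record_like <- function(template, amplitude, stage = NULL) {
  ppg_record(amplitude,
    fs = ppg_fs(template),
    record_id = attr(template, "record_id") %||% "rec",
    condition = attr(template, "condition") %||% "synthetic",
    stage = stage %||% attr(template, "stage") %||% "raw"
  )
}

#' Sampling frequency of a record or annotation
#' @param x A `ppg_record` or `peak_annotation`.
#' @return Sampling frequency in Hz.
#' @export
ppg_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) validation_error("object carries no `fs` attribute")
  fs
}

#' Construct a peak annotation
#'
#' An ordered set of systolic-peak sample positions (1-based) for a record.
#' Input indices are sorted and de-duplicated; out-of-range or non-positive
#' indices are an error.
#'
#' @param index Integer vector of 1-based sample positions.
#' @param fs Sampling frequency in Hz of the annotated record.
#' @param n_samples Optional record length used to range-check indices.
#' @return A `peak_annotation` tibble with column `index`.
#' @examples
#' peak_annotation(c(250, 10, 480), fs = 367)
#' @export
peak_annotation <- function(index, fs = 367, n_samples = NULL) {
  if (length(index) > 0) {
    if (!is.numeric(index) || any(!is.finite(index)) ||
        any(index != floor(index))) {
      validation_error("`index` must contain whole numbers")
    }
    if (any(index < 1)) {
      validation_error("peak indices must be >= 1 (1-based sample positions)")
    }
    if (!is.null(n_samples) && any(index > n_samples)) {
      validation_error("peak index beyond record length")
    }
  }
  check_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  idx <- sort(unique(as.integer(index)))
  out <- tibble(index = idx)
  structure(out, class = c("peak_annotation", class(out)), fs = fs)
}

peak_indices <- function(x) {
  if (inherits(x, "peak_annotation") || (is.data.frame(x) && "index" %in% names(x))) {
    return(as.integer(x$index))
  }
  as.integer(x)
}

#' Read a PPG record from delimited text
#'
#' Accepts one numeric column (amplitude) or two (time, amplitude; the time
#' column is discarded and rebuilt from `fs`). The delimiter is sniffed:
#' comma, tab or whitespace. Lines starting with `#` are ignored.
#'
#' @param path Path to the text file.
#' @inheritParams ppg_record
#' @return A `ppg_record`.
#' @export
read_ppg_record <- function(path, fs = 367, record_id = NULL,
                            condition = "synthetic") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ppgpeaks_io_error")
  }
  check_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) parse_error(sprintf("no data lines in %s", path))
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  dat <- tryCatch(
    read.table(text = lines, sep = sep, header = FALSE,
               colClasses = "numeric", strip.white = TRUE),
    error = function(e) parse_error(sprintf("non-numeric payload in %s", path)),
    warning = function(w) parse_error(sprintf("non-numeric payload in %s", path))
  )
  if (ncol(dat) > 2) parse_error("expected one or two columns")
  amp <- dat[[ncol(dat)]]
  if (any(!is.finite(amp))) parse_error("non-finite amplitude values")
  ppg_record(amp, fs = fs,
             record_id = record_id %||% tools::file_path_sans_ext(basename(path)),
             condition = condition)
}

#' Write a PPG record as single-column text
#' @param x A `ppg_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppg_record <- function(x, path) {
  writeLines(format(x$amplitude, digits = 15, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read a peak annotation file
#'
#' One integer sample index (1-based) per line; `#` comments and blank lines
#' allowed; CRLF accepted. Indices are sorted and de-duplicated on read.
#'
#' @param path Path to the annotation file.
#' @param fs Sampling frequency in Hz.
#' @return A `peak_annotation`.
#' @export
read_peak_annotation <- function(path, fs = 367) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ppgpeaks_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(peak_annotation(integer(0), fs = fs))
  }
  idx <- suppressWarnings(as.numeric(lines))
  if (any(is.na(idx))) parse_error(sprintf("non-integer line in %s", path))
  peak_annotation(idx, fs = fs)
}

#' Write a peak annotation file (one index per line)
#' @param x A `peak_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_annotation <- function(x, path) {
  writeLines(as.character(peak_indices(x)), path)
  invisible(path)
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("# PPG record '%s' (%s, stage %s): %d samples @ %g Hz (%.2f s)\n",
              attr(x, "record_id"), attr(x, "condition"), attr(x, "stage"),
              nrow(x), ppg_fs(x), nrow(x) / ppg_fs(x)))
  NextMethod()
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("# Peak annotation: %d peaks @ %g Hz\n", nrow(x), ppg_fs(x)))
  NextMethod()
}
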