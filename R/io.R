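#' Read a timestamped tri-axial sensor file
#'
#' Reads delimited text (CSV/TSV, header row) with one timestamp column and
#' three measurement columns. Column names are configurable because exports
#' from different phone apps label them differently. Timestamps may be
#' numeric seconds or ISO-8601 date-times; date-times are normalized to
#' numeric seconds (POSIX epoch) at read time.
#'
#' @param path Path to the delimited file.
#' @param sensor_kind `"accelerometer"` or `"gyroscope"`.
#' @param nominal_hz Nominal sampling frequency in Hz.
#' @param columns Named character vector mapping the canonical names
#'   `time`, `x`, `y`, `z` to the file's column names.
#' @param delim Field delimiter, default `","`.
#' @return A [sensor_stream()].
#' @export
read_stream <- function(path,
                        sensor_kind = c("accelerometer", "gyroscope"),
                        nominal_hz = 10,
                        columns = c(time = "timestamp", x = "x", y = "y", z = "z"),
                        delim = ",") {
  sensor_kind <- match.arg(sensor_kind)
  canonical <- c("time", "x", "y", "z")
  if (!all(canonical %in% names(columns))) {
    abort("`columns` must name all of time, x, y, z",
          class = "moveletr_format_error")
  }
  # columns come back as text and are parsed with strtod (correctly
  # rounded), so written values are recovered bit-exactly
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing_cols <- setdiff(unname(columns[canonical]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveletr_format_error")
  }
  if (nrow(raw) < 1) {
    abort(paste0("file ", path, " contains no data rows"),
          class = "moveletr_empty_input_error")
  }
  out <- tibble::tibble(
    time = parse_timestamps(raw[[columns[["time"]]]], path),
    x = parse_numeric_column(raw[[columns[["x"]]]], columns[["x"]], path),
    y = parse_numeric_column(raw[[columns[["y"]]]], columns[["y"]], path),
    z = parse_numeric_column(raw[[columns[["z"]]]], columns[["z"]], path)
  )
  sensor_stream(out, sensor_kind = sensor_kind, nominal_hz = nominal_hz)
}

# Numeric passthrough; ISO-8601 date-times become seconds since the epoch.
parse_timestamps <- function(v, path) {
  if (is.numeric(v)) return(as.numeric(v))
  if (inherits(v, "POSIXct")) return(as.numeric(v))
  as_num <- suppressWarnings(as.numeric(v))
  if (!anyNA(as_num)) return(as_num)
  parsed <- readr::parse_datetime(as.character(v))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed))[1]
    abort(paste0("file ", path, ": timestamp not numeric seconds or ",
                 "ISO-8601 at data row ", bad),
          class = "moveletr_parse_error")
  }
  as.numeric(parsed)
}

parse_numeric_column <- function(v, name, path) {
  if (is.numeric(v)) return(as.numeric(v))
  parsed <- suppressWarnings(as.numeric(v))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed))[1]
    abort(paste0("file ", path, ": non-numeric value in column '", name,
                 "' at data row ", bad),
          class = "moveletr_parse_error")
  }
  parsed
}

# Delimited writer with guaranteed numeric round-trip: doubles are printed
# with 17 significant digits, enough to reproduce any double exactly.
write_delim_precise <- function(df, path, delim = ",") {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Write a sensor stream to delimited text
#'
#' Values are written with shortest round-trip precision, so
#' `read_stream(write_stream(s))` reproduces `s` exactly.
#'
#' @param stream A [sensor_stream()].
#' @param path Output path.
#' @param columns Column-name mapping as in [read_stream()].
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path,
                         columns = c(time = "timestamp", x = "x", y = "y", z = "z"),
                         delim = ",") {
  out <- as.data.frame(stream)[, c("time", "x", "y", "z")]
  names(out) <- unname(columns[c("time", "x", "y", "z")])
  write_delim_precise(out, path, delim = delim)
  invisible(path)
}

#' Read activity-interval annotations
#'
#' Annotations are labeled time intervals `[start, end)` in a CSV with
#' header columns `label`, `start`, `end`. Intervals are returned sorted by
#' start time. Overlapping intervals are rejected unless
#' `allow_overlap = TRUE`, because overlapping ground truth makes
#' per-timestamp labels ambiguous.
#'
#' @param path Path to the annotation CSV.
#' @param allow_overlap Permit overlapping intervals (default `FALSE`).
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
read_intervals <- function(path, allow_overlap = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("label", "start", "end"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveletr_format_error")
  }
  activity_intervals(
    tibble::tibble(label = as.character(raw$label),
                   start = as.numeric(raw$start),
                   end = as.numeric(raw$end)),
    allow_overlap = allow_overlap
  )
}

#' Validate a table of activity intervals
#'
#' @param intervals Data frame with columns `label`, `start`, `end`.
#' @param allow_overlap Permit overlapping intervals.
#' @return A tibble sorted by `start`.
#' @export
activity_intervals <- function(intervals, allow_overlap = FALSE) {
  out <- tibble::as_tibble(intervals)[, c("label", "start", "end")]
  if (any(!nzchar(out$label)) || anyNA(out$label)) {
    abort("interval labels must be non-empty", class = "moveletr_format_error")
  }
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1]
    abort(paste0("interval ", bad, " ('", out$label[bad],
                 "') has end <= start"),
          class = "moveletr_format_error")
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (!allow_overlap && nrow(out) > 1) {
    overlap <- out$start[-1] < out$end[-nrow(out)]
    if (any(overlap)) {
      bad <- which(overlap)[1]
      abort(paste0("intervals ", bad, " and ", bad + 1,
                   " overlap; pass allow_overlap = TRUE to permit"),
            class = "moveletr_overlap_error")
    }
  }
  out
}

#' Write activity intervals to CSV
#'
#' @param intervals A tibble with columns `label`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  write_delim_precise(
    tibble::as_tibble(intervals)[, c("label", "start", "end")], path)
  invisible(path)
}

#' Convert interval annotations to per-timestamp labels
#'
#' Each timestamp `t` receives the label of the interval with
#' `start <= t < end`; timestamps covered by no interval receive `NA` (the
#' unlabeled sentinel), so downstream evaluation can exclude them
#' explicitly rather than silently dropping samples.
#'
#' @param intervals A tibble with columns `label`, `start`, `end`.
#' @param timestamps Strictly increasing numeric vector of seconds.
#' @return A label series: tibble with columns `time`, `label`.
#' @export
#' @examples
#' intervals_to_labels(
#'   data.frame(label = "walk", start = 0, end = 1),
#'   timestamps = c(0, 0.5, 1)
#' )
intervals_to_labels <- function(intervals, timestamps) {
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    abort("timestamps must be strictly increasing",
          class = "moveletr_format_error")
  }
  intervals <- tibble::as_tibble(intervals)
  labels <- rep(NA_character_, length(timestamps))
  if (nrow(intervals) > 0) {
    hits <- integer(length(timestamps))
    for (i in seq_len(nrow(intervals))) {
      covered <- timestamps >= intervals$start[i] & timestamps < intervals$end[i]
      if (any(covered & hits > 0)) {
        abort("overlapping intervals cover the same timestamp",
              class = "moveletr_overlap_error")
      }
      hits[covered] <- i
      labels[covered] <- intervals$label[i]
    }
  }
  label_series(timestamps, labels)
}

#' Construct a label series
#'
#' A label series pairs a strictly increasing timestamp vector with one
#' activity label (or `NA`, the unlabeled sentinel) per timestamp. Both
#' ground-truth annotations aligned to a sample grid and classifier output
#' take this form.
#'
#' @param time Strictly increasing numeric vector of seconds.
#' @param label Character vector of the same length.
#' @param ... Additional equal-length columns (e.g. `best_distance`).
#' @return A tibble of class `label_series`.
#' @export
label_series <- function(time, label, ...) {
  if (length(time) != length(label)) {
    abort("time and label must have equal length",
          class = "moveletr_format_error")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    abort("timestamps must be strictly increasing",
          class = "moveletr_format_error")
  }
  out <- tibble::tibble(time = as.numeric(time),
                        label = as.character(label), ...)
  class(out) <- c("label_series", class(tibble::tibble()))
  out
}

#' Read / write a label series CSV
#'
#' The CSV has columns `timestamp`, `predicted_label` and optionally
#' `best_distance`.
#'
#' @param labels A [label_series()].
#' @param path File path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()` a
#'   [label_series()].
#' @export
write_labels <- function(labels, path) {
  out <- data.frame(timestamp = labels$time, predicted_label = labels$label)
  if ("best_distance" %in% names(labels)) {
    out$best_distance <- labels$best_distance
  }
  write_delim_precise(out, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "")
  lab <- as.character(raw$predicted_label)
  lab[!is.na(lab) & !nzchar(lab)] <- NA_character_
  extra <- if ("best_distance" %in% names(raw)) {
    list(best_distance = as.numeric(raw$best_distance))
  } else {
    list()
  }
  do.call(label_series, c(list(time = raw$timestamp, label = lab), extra))
}
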