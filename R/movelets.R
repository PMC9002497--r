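#' Extract sliding-window movelets from a stream
#'
#' A movelet is a fixed-length window of a stream's samples: at 10 Hz the
#' default `window_samples = 10` gives the canonical 1-s movelet. Windows
#' slide forward one sample at a time, so a stream of `N` samples yields
#' `N - window_samples + 1` movelets; consecutive movelets share
#' `window_samples - 1` samples. Raw values are stored without any
#' normalization or filtering.
#'
#' @param stream A [sensor_stream()] (3 channels) or [joint_stream()]
#'   (6 channels).
#' @param window_samples Positive integer window length in samples.
#' @return A tibble with columns `start_time` (timestamp of the window's
#'   first sample) and `values` (list of channels-by-samples matrices with
#'   channel rownames).
#' @export
#' @examples
#' s <- sensor_stream(data.frame(time = 0:49 / 10, x = rnorm(50),
#'                               y = rnorm(50), z = rnorm(50)))
#' nrow(extract_movelets(s, 10)) # 41 movelets from 5 s at 10 Hz
extract_movelets <- function(stream, window_samples = 10) {
  window_samples <- as.integer(window_samples)
  if (window_samples < 1) {
    abort("window_samples must be a positive integer",
          class = "moveletr_format_error")
  }
  n <- nrow(stream)
  if (n < window_samples) {
    abort(sprintf(
      "stream has %d samples but a window needs %d (%d short)",
      n, window_samples, window_samples - n
    ), class = "moveletr_insufficient_data_error")
  }
  mat <- t(stream_matrix(stream)) # channels x samples
  starts <- seq_len(n - window_samples + 1L)
  tibble::tibble(
    start_time = stream$time[starts],
    values = lapply(starts, function(i) {
      mat[, i:(i + window_samples - 1L), drop = FALSE]
    })
  )
}

#' Build a per-participant movelet dictionary
#'
#' The dictionary maps each activity to all sliding-window movelets of that
#' activity's training segment. Segments may repeat an activity name (e.g.
#' two bouts of walking); their movelets are pooled under one entry.
#' Construction is deterministic and the entry contents do not depend on
#' the order in which activities are listed; the declared `activities`
#' order is retained only as the deterministic tie-break order used during
#' classification.
#'
#' @param segments Named list of streams, one per training segment; names
#'   are activity labels. All segments must share the channel count.
#' @param window_samples Window length in samples (default 10).
#' @param activities Optional character vector fixing the dictionary's
#'   activity order; defaults to first appearance in `segments`.
#' @return An object of class `movelet_dictionary`: a list with elements
#'   `movelets` (tibble with columns `activity`, `index`, `start_time`,
#'   `values`), `activities`, `n_channels`, `window_samples`.
#' @export
build_dictionary <- function(segments, window_samples = 10,
                             activities = NULL) {
  if (length(segments) == 0 || is.null(names(segments)) ||
      any(!nzchar(names(segments)))) {
    abort("segments must be a non-empty named list of streams",
          class = "moveletr_format_error")
  }
  channel_sets <- vapply(segments, function(s) length(stream_channels(s)), 0L)
  if (length(unique(channel_sets)) != 1) {
    abort("all training segments must share the same channel count",
          class = "moveletr_dimension_error")
  }
  activities <- activities %||% unique(names(segments))
  per_segment <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    if (nrow(seg) < window_samples) {
      abort(sprintf(
        "training segment for activity '%s' has %d samples; %d needed for one window",
        names(segments)[i], nrow(seg), as.integer(window_samples)
      ), class = "moveletr_insufficient_data_error")
    }
    mv <- extract_movelets(seg, window_samples)
    mv$activity <- names(segments)[i]
    per_segment[[i]] <- mv
  }
  all_mv <- dplyr::bind_rows(per_segment)
  # canonical order: declared activity order, then start time within activity
  all_mv <- all_mv[order(match(all_mv$activity, activities)), , drop = FALSE]
  all_mv <- dplyr::group_by(all_mv, .data$activity)
  all_mv <- dplyr::mutate(all_mv, index = dplyr::row_number())
  all_mv <- dplyr::ungroup(all_mv)
  structure(
    list(
      movelets = all_mv[, c("activity", "index", "start_time", "values")],
      activities = activities,
      n_channels = nrow(all_mv$values[[1]]),
      window_samples = as.integer(window_samples)
    ),
    class = "movelet_dictionary"
  )
}

#' @rdname build_dictionary
#' @param x An object.
#' @export
is_movelet_dictionary <- function(x) inherits(x, "movelet_dictionary")

#' Build a dictionary from a labeled recording
#'
#' Convenience wrapper: cuts training segments out of a single stream using
#' interval annotations, truncates each to `max_seconds`, and builds the
#' dictionary.
#'
#' @param stream A [sensor_stream()] or [joint_stream()] covering the
#'   training recording.
#' @param intervals Interval annotations (`label`, `start`, `end`).
#' @param window_samples Window length in samples.
#' @param max_seconds Per-segment training duration cap in seconds
#'   (default 5); `NULL` disables truncation.
#' @return A `movelet_dictionary`.
#' @export
dictionary_from_annotations <- function(stream, intervals,
                                        window_samples = 10,
                                        max_seconds = 5) {
  intervals <- tibble::as_tibble(intervals)
  segments <- lapply(seq_len(nrow(intervals)), function(i) {
    seg <- clip_stream(stream, intervals$start[i], intervals$end[i])
    if (!is.null(max_seconds)) seg <- truncate_training(seg, max_seconds)
    seg
  })
  names(segments) <- intervals$label
  build_dictionary(segments, window_samples,
                   activities = unique(intervals$label))
}

#' Truncate a training segment to a maximum duration
#'
#' Keeps the leading portion of the segment: samples with
#' `time - time[1] < max_seconds` (so at 10 Hz a 5-s cap keeps 50 samples).
#' Segments already shorter than the cap are returned unchanged; momentary
#' transition activities typically are.
#'
#' @param segment A [sensor_stream()] or [joint_stream()].
#' @param max_seconds Positive duration cap in seconds.
#' @return A stream of the same class.
#' @export
truncate_training <- function(segment, max_seconds) {
  stopifnot(max_seconds > 0)
  keep <- segment$time - segment$time[1] < max_seconds
  out <- segment[keep, , drop = FALSE]
  attr(out, "sensor_kind") <- attr(segment, "sensor_kind")
  attr(out, "nominal_hz") <- attr(segment, "nominal_hz")
  class(out) <- class(segment)
  out
}

#' Serialize a dictionary to CSV (and back)
#'
#' The long format has one row per stored value:
#' `(activity, movelet_index, start_time, channel, sample_index, value)`.
#' Values round-trip exactly (shortest round-trip precision).
#'
#' @param dictionary A `movelet_dictionary`.
#' @param path Output path.
#' @return `write_dictionary()` returns `path` invisibly;
#'   `read_dictionary()` the reloaded `movelet_dictionary`.
#' @export
write_dictionary <- function(dictionary, path) {
  mv <- dictionary$movelets
  long <- purrr::pmap_dfr(
    list(mv$activity, mv$index, mv$start_time, mv$values),
    function(activity, index, start_time, values) {
      tibble::tibble(
        activity = activity, movelet_index = index, start_time = start_time,
        channel = rep(rownames(values), each = ncol(values)),
        sample_index = rep(seq_len(ncol(values)), times = nrow(values)),
        value = as.vector(t(values))
      )
    }
  )
  write_delim_precise(long, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  long$movelet_index <- as.integer(long$movelet_index)
  long$start_time <- as.numeric(long$start_time)
  long$sample_index <- as.integer(long$sample_index)
  long$value <- as.numeric(long$value) # strtod: exact round trip
  channels <- unique(long$channel)
  window_samples <- max(long$sample_index)
  keys <- dplyr::distinct(long, .data$activity, .data$movelet_index,
                          .data$start_time)
  long <- long[order(match(long$activity, unique(keys$activity)),
                     long$movelet_index,
                     match(long$channel, channels),
                     long$sample_index), , drop = FALSE]
  values <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- long$activity == keys$activity[i] &
      long$movelet_index == keys$movelet_index[i]
    matrix(long$value[rows], nrow = length(channels), byrow = TRUE,
           dimnames = list(channels, NULL))
  })
  structure(
    list(
      movelets = tibble::tibble(activity = keys$activity,
                                index = keys$movelet_index,
                                start_time = keys$start_time,
                                values = values),
      activities = unique(keys$activity),
      n_channels = length(channels),
      window_samples = as.integer(window_samples)
    ),
    class = "movelet_dictionary"
  )
}

#' @export
print.movelet_dictionary <- function(x, ...) {
  counts <- table(factor(x$movelets$activity, levels = x$activities))
  cat(sprintf("<movelet_dictionary: %d activities, %d movelets, %d channels x %d samples>\n",
              length(x$activities), nrow(x$movelets), x$n_channels,
              x$window_samples))
  for (a in x$activities) {
    cat(sprintf("  %-14s %d movelets\n", a, counts[[a]]))
  }
  invisible(x)
}

#' Tidy a movelet dictionary
#'
#' @param x A `movelet_dictionary`.
#' @param ... Unused.
#' @return `tidy()`: one row per movelet (`activity`, `index`,
#'   `start_time`). `glance()`: a one-row summary (`n_activities`,
#'   `n_movelets`, `n_channels`, `window_samples`).
#' @export
tidy.movelet_dictionary <- function(x, ...) {
  x$movelets[, c("activity", "index", "start_time")]
}

#' @rdname tidy.movelet_dictionary
#' @export
glance.movelet_dictionary <- function(x, ...) {
  tibble::tibble(
    n_activities = length(x$activities),
    n_movelets = nrow(x$movelets),
    n_channels = x$n_channels,
    window_samples = x$window_samples
  )
}
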