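#' Construct a tri-axial sensor stream
#'
#' A sensor stream is a tibble with columns `time`, `x`, `y`, `z` holding one
#' tri-axial sensor's timestamped measurements: accelerometer in units of g,
#' gyroscope in rad/s. Timestamps are real seconds relative to an arbitrary
#' epoch and must be strictly increasing. The nominal sampling frequency is
#' carried as metadata so window lengths in seconds can be converted to
#' sample counts.
#'
#' @param data A data frame with numeric columns `time`, `x`, `y`, `z`.
#' @param sensor_kind `"accelerometer"` or `"gyroscope"`.
#' @param nominal_hz Positive nominal sampling frequency in Hz.
#'
#' @return A tibble of class `sensor_stream` with attributes `sensor_kind`
#'   and `nominal_hz`.
#' @export
#' @examples
#' sensor_stream(
#'   data.frame(time = c(0, 0.1, 0.2), x = 0, y = 0, z = 1),
#'   sensor_kind = "accelerometer", nominal_hz = 10
#' )
sensor_stream <- function(data,
                          sensor_kind = c("accelerometer", "gyroscope"),
                          nominal_hz = 10) {
  sensor_kind <- match.arg(sensor_kind)
  missing_cols <- setdiff(c("time", "x", "y", "z"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "sensor stream is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "moveletr_format_error")
  }
  out <- tibble::as_tibble(data)[, c("time", "x", "y", "z")]
  for (col in names(out)) {
    if (!is.numeric(out[[col]])) {
      abort(paste0("column '", col, "' must be numeric"),
            class = "moveletr_parse_error")
    }
  }
  if (nrow(out) < 1) {
    abort("sensor stream must contain at least one sample",
          class = "moveletr_empty_input_error")
  }
  if (anyNA(out)) {
    abort("sensor stream contains missing values",
          class = "moveletr_parse_error")
  }
  if (nrow(out) > 1 && any(diff(out$time) <= 0)) {
    bad <- which(diff(out$time) <= 0)[1] + 1L
    abort(paste0("timestamps must be strictly increasing (violated at row ",
                 bad, ")"),
          class = "moveletr_format_error")
  }
  if (!is.numeric(nominal_hz) || length(nominal_hz) != 1 || nominal_hz <= 0) {
    abort("nominal_hz must be a positive number",
          class = "moveletr_format_error")
  }
  structure(out,
            class = c("sensor_stream", class(tibble::tibble())),
            sensor_kind = sensor_kind,
            nominal_hz = as.numeric(nominal_hz))
}

#' @rdname sensor_stream
#' @param x An object.
#' @export
is_sensor_stream <- function(x) inherits(x, "sensor_stream")

#' Sensor-stream metadata accessors
#'
#' @param stream A [sensor_stream()].
#' @return `sensor_kind()` returns the sensor type string; `nominal_hz()` the
#'   nominal sampling frequency in Hz.
#' @export
sensor_kind <- function(stream) attr(stream, "sensor_kind")

#' @rdname sensor_kind
#' @export
nominal_hz <- function(stream) attr(stream, "nominal_hz")

#' Construct a joint (six-channel) sensor stream
#'
#' A joint stream carries accelerometer and gyroscope measurements on a
#' common timestamp grid (the accelerometer's), with six channels in fixed
#' order: `xa`, `ya`, `za` (accelerometer, g) then `xg`, `yg`, `zg`
#' (gyroscope interpolated to the accelerometer timestamps, rad/s).
#'
#' @param data Data frame with numeric columns `time`, `xa`, `ya`, `za`,
#'   `xg`, `yg`, `zg`.
#' @param nominal_hz Positive nominal sampling frequency in Hz.
#' @param dropped Optional named integer vector recording how many leading /
#'   trailing accelerometer samples were dropped because they fell outside
#'   the gyroscope's observed span.
#' @return A tibble of class `joint_stream`.
#' @seealso [build_joint_stream()]
#' @export
joint_stream <- function(data, nominal_hz = 10,
                         dropped = c(leading = 0L, trailing = 0L)) {
  cols <- c("time", JOINT_CHANNELS)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("joint stream is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "moveletr_format_error")
  }
  out <- tibble::as_tibble(data)[, cols]
  if (nrow(out) < 1) {
    abort("joint stream must contain at least one sample",
          class = "moveletr_empty_input_error")
  }
  if (nrow(out) > 1 && any(diff(out$time) <= 0)) {
    abort("timestamps must be strictly increasing",
          class = "moveletr_format_error")
  }
  structure(out,
            class = c("joint_stream", class(tibble::tibble())),
            nominal_hz = as.numeric(nominal_hz),
            dropped = dropped)
}

#' @rdname joint_stream
#' @param x An object.
#' @export
is_joint_stream <- function(x) inherits(x, "joint_stream")

# Channel names of a stream's measurement columns, in canonical order.
stream_channels <- function(stream) {
  if (is_joint_stream(stream)) JOINT_CHANNELS else AXIS_CHANNELS
}

# Measurement columns as a plain numeric matrix (samples x channels).
stream_matrix <- function(stream) {
  as.matrix(as.data.frame(stream)[, stream_channels(stream), drop = FALSE])
}

#' Restrict a stream to a time window
#'
#' Keeps samples with `start <= time < end` (half-open, so adjacent windows
#' partition the recording without double-counting boundary samples).
#'
#' @param stream A [sensor_stream()] or [joint_stream()].
#' @param start,end Window bounds in seconds.
#' @return A stream of the same class. Errors if the window is empty.
#' @export
clip_stream <- function(stream, start, end) {
  keep <- stream$time >= start & stream$time < end
  if (!any(keep)) {
    abort("no samples fall inside the requested window",
          class = "moveletr_empty_input_error")
  }
  out <- stream[keep, , drop = FALSE]
  attributes_to_keep <- attributes(stream)
  attr(out, "sensor_kind") <- attributes_to_keep$sensor_kind
  attr(out, "nominal_hz") <- attributes_to_keep$nominal_hz
  class(out) <- class(stream)
  out
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream: %s, %d samples, nominal %g Hz, span [%g, %g] s>\n",
              sensor_kind(x), nrow(x), nominal_hz(x),
              x$time[1], x$time[nrow(x)]))
  NextMethod()
}

#' @export
print.joint_stream <- function(x, ...) {
  dropped <- attr(x, "dropped")
  cat(sprintf("<joint_stream: %d samples, nominal %g Hz, dropped %d leading / %d trailing accel samples>\n",
              nrow(x), attr(x, "nominal_hz"),
              dropped[["leading"]], dropped[["trailing"]]))
  NextMethod()
}
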