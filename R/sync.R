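#' Linearly interpolate a stream to new timestamps
#'
#' Each axis is interpolated independently with linear interpolation
#' (`stats::approx`). No extrapolation is performed: target timestamps
#' outside `[min(source$time), max(source$time)]` are dropped, and the
#' retained-timestamp mask is attached so callers can see which targets
#' survived. Fabricating measurements beyond the observed span would bias
#' boundary movelets, so out-of-span targets are reported rather than
#' filled.
#'
#' @param source A [sensor_stream()] with at least two samples.
#' @param target_timestamps Strictly increasing numeric vector of seconds.
#' @return A [sensor_stream()] on the retained target timestamps, with a
#'   logical attribute `retained` (one entry per target timestamp).
#' @export
interpolate_to <- function(source, target_timestamps) {
  if (nrow(source) < 2) {
    abort("interpolation requires at least two source samples",
          class = "moveletr_empty_input_error")
  }
  if (length(target_timestamps) > 1 && any(diff(target_timestamps) <= 0)) {
    abort("target timestamps must be strictly increasing",
          class = "moveletr_format_error")
  }
  span <- range(source$time)
  retained <- target_timestamps >= span[1] & target_timestamps <= span[2]
  if (!any(retained)) {
    abort("no target timestamp falls inside the source stream's time span",
          class = "moveletr_empty_overlap_error")
  }
  tt <- target_timestamps[retained]
  interp_axis <- function(v) approx(source$time, v, xout = tt,
                                    method = "linear", ties = "ordered")$y
  out <- sensor_stream(
    tibble::tibble(time = tt,
                   x = interp_axis(source$x),
                   y = interp_axis(source$y),
                   z = interp_axis(source$z)),
    sensor_kind = sensor_kind(source),
    nominal_hz = nominal_hz(source)
  )
  attr(out, "retained") <- retained
  out
}

#' Build the six-channel joint stream
#'
#' Synchronizes a gyroscope stream to the accelerometer timestamp grid by
#' linear interpolation and concatenates the channels in the fixed order
#' (`xa`, `ya`, `za`, `xg`, `yg`, `zg`). The output timestamps are exactly
#' the accelerometer timestamps covered by the gyroscope's observed span;
#' accelerometer samples without a bracketing pair of gyroscope samples are
#' dropped, and the drop counts are recorded on the result.
#'
#' @param accel Accelerometer [sensor_stream()].
#' @param gyro Gyroscope [sensor_stream()] with at least two samples.
#' @return A [joint_stream()]; accelerometer channels are copied unchanged
#'   for the retained timestamps.
#' @export
#' @examples
#' accel <- sensor_stream(data.frame(time = 0:9 / 10, x = 0, y = 1, z = 0))
#' gyro <- sensor_stream(data.frame(time = 0:9 / 10, x = 0.2, y = 0, z = 0),
#'                       sensor_kind = "gyroscope")
#' build_joint_stream(accel, gyro)
build_joint_stream <- function(accel, gyro) {
  stopifnot(is_sensor_stream(accel), is_sensor_stream(gyro))
  gi <- interpolate_to(gyro, accel$time)
  retained <- attr(gi, "retained")
  acc <- accel[retained, , drop = FALSE]
  n_lead <- if (length(retained)) match(TRUE, retained) - 1L else 0L
  n_trail <- length(retained) - max(which(retained))
  joint_stream(
    tibble::tibble(time = acc$time,
                   xa = acc$x, ya = acc$y, za = acc$z,
                   xg = gi$x, yg = gi$y, zg = gi$z),
    nominal_hz = nominal_hz(accel),
    dropped = c(leading = n_lead, trailing = as.integer(n_trail))
  )
}
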