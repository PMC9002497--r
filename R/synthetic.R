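#' Define a synthetic activity signal model
#'
#' Each activity is modeled per sensor as a baseline 3-vector plus, for
#' locomotion, a per-axis sinusoid (amplitude, shared frequency, per-axis
#' phase), or, for postural transitions, a smoothstep blend between the two
#' neighboring postures' baselines with a gyroscope arc that starts and
#' ends at zero. Gaussian i.i.d. noise is added per sample.
#'
#' @param name Activity name.
#' @param kind `"stationary"`, `"periodic"` or `"transition"`.
#' @param accel_baseline,gyro_baseline Length-3 baselines (g, rad/s).
#' @param accel_amp,gyro_amp Length-3 sinusoid amplitudes (periodic only).
#' @param freq Oscillation frequency in Hz (periodic only; > 0).
#' @param accel_phase,gyro_phase Length-3 phase offsets in radians.
#' @param accel_from,accel_to Length-3 start/end accelerometer baselines
#'   (transition only).
#' @param gyro_arc_amp Length-3 gyroscope arc amplitudes (transition only).
#' @param variable_start Transition only: add a damped early oscillation to
#'   the gyroscope arc (stand-to-sit starts more variably than
#'   sit-to-stand).
#' @param noise_sd Named length-2 vector `c(accel = , gyro = )` of noise
#'   standard deviations (g, rad/s); non-negative.
#' @return A list of class `activity_model`.
#' @export
activity_model <- function(name,
                           kind = c("stationary", "periodic", "transition"),
                           accel_baseline = c(0, 0, 0),
                           gyro_baseline = c(0, 0, 0),
                           accel_amp = c(0, 0, 0),
                           gyro_amp = c(0, 0, 0),
                           freq = 1,
                           accel_phase = c(0, 0, 0),
                           gyro_phase = c(0, 0, 0),
                           accel_from = NULL,
                           accel_to = NULL,
                           gyro_arc_amp = c(0, 0, 0),
                           variable_start = FALSE,
                           noise_sd = c(accel = 0.02, gyro = 0.02)) {
  kind <- match.arg(kind)
  if (any(noise_sd < 0)) {
    abort("noise_sd must be non-negative", class = "moveletr_format_error")
  }
  if (kind == "periodic" && freq <= 0) {
    abort("periodic models need freq > 0", class = "moveletr_format_error")
  }
  if (kind == "transition" &&
      (is.null(accel_from) || is.null(accel_to))) {
    abort("transition models need accel_from and accel_to",
          class = "moveletr_format_error")
  }
  structure(
    list(name = name, kind = kind,
         accel_baseline = accel_baseline, gyro_baseline = gyro_baseline,
         accel_amp = accel_amp, gyro_amp = gyro_amp, freq = freq,
         accel_phase = accel_phase, gyro_phase = gyro_phase,
         accel_from = accel_from, accel_to = accel_to,
         gyro_arc_amp = gyro_arc_amp, variable_start = variable_start,
         noise_sd = noise_sd),
    class = "activity_model"
  )
}

#' Default signal models for the seven dictionary activities
#'
#' The defaults encode the characteristic signatures of phone-in-pocket
#' sensing: standing holds the accelerometer near (-0.15, +0.98, 0.02) g
#' (phone vertical, gravity on y), sitting near (-0.73, 0.26, 0.64) g
#' (phone tilted in the pocket); the gyroscope is identically zero-mean for
#' both stationary postures, so a gyroscope alone cannot tell sitting from
#' standing. Walking and stair climbing are quasi-periodic with distinct
#' frequencies, amplitudes and phases per activity (walking's x and y
#' accelerometer axes oscillate out of phase; the gyroscope axes are more
#' synchronized). The two postural transitions blend smoothly between the
#' standing and sitting baselines with gyroscope arcs that start and end at
#' zero; the stand-to-sit arc is more variable at its beginning.
#'
#' @param noise_sd Named length-2 vector of per-sensor noise standard
#'   deviations, applied to every model (default 0.02 g / 0.02 rad/s).
#' @return Named list of [activity_model()]s for `walk`, `stand`,
#'   `stairUp`, `stairDown`, `sit`, `sit-to-stand`, `stand-to-sit`.
#' @export
default_models <- function(noise_sd = c(accel = 0.02, gyro = 0.02)) {
  stand_acc <- c(-0.15, 0.98, 0.02)
  sit_acc <- c(-0.73, 0.26, 0.64)
  list(
    walk = activity_model(
      "walk", "periodic",
      accel_baseline = c(-0.20, 0.95, 0.10),
      accel_amp = c(0.25, 0.25, 0.35), freq = 2.0,
      accel_phase = c(0, pi, pi / 3), # x/y out of phase
      gyro_amp = c(0.80, 0.80, 0.60),
      gyro_phase = c(0, 0.3, 0.6),
      noise_sd = noise_sd
    ),
    stand = activity_model(
      "stand", "stationary",
      accel_baseline = stand_acc, gyro_baseline = c(0, 0, 0),
      noise_sd = noise_sd
    ),
    stairUp = activity_model(
      "stairUp", "periodic",
      accel_baseline = c(-0.25, 0.90, 0.15),
      accel_amp = c(0.20, 0.30, 0.50), freq = 1.6,
      accel_phase = c(0, pi, pi / 2),
      gyro_amp = c(1.10, 0.60, 0.90),
      gyro_phase = c(0, 0.3, 0.6),
      noise_sd = noise_sd
    ),
    stairDown = activity_model(
      "stairDown", "periodic",
      accel_baseline = c(-0.20, 0.92, 0.05),
      accel_amp = c(0.30, 0.35, 0.60), freq = 1.8,
      accel_phase = c(0, pi, 2 * pi / 3),
      gyro_amp = c(1.30, 0.90, 1.10),
      gyro_phase = c(0, 0.2, 0.4),
      noise_sd = noise_sd
    ),
    sit = activity_model(
      "sit", "stationary",
      accel_baseline = sit_acc, gyro_baseline = c(0, 0, 0),
      noise_sd = noise_sd
    ),
    `sit-to-stand` = activity_model(
      "sit-to-stand", "transition",
      accel_from = sit_acc, accel_to = stand_acc,
      gyro_arc_amp = c(0.90, 0.70, 0.50),
      variable_start = FALSE,
      noise_sd = noise_sd
    ),
    `stand-to-sit` = activity_model(
      "stand-to-sit", "transition",
      accel_from = stand_acc, accel_to = sit_acc,
      gyro_arc_amp = c(-0.90, -0.70, -0.50),
      variable_start = TRUE,
      noise_sd = noise_sd
    )
  )
}

#' Models with a shared accelerometer signature
#'
#' Returns the default models with the `target` activity's accelerometer
#' parameters replaced by the `source` activity's, leaving the gyroscope
#' parameters distinct. Under these models the accelerometer alone cannot
#' separate the two activities but the gyroscope (and hence the
#' joint-sensor mode) can — the mirror image of the sitting/standing
#' situation, used to probe sensor fusion from the other side.
#'
#' @param source,target Activity names (defaults `"walk"`, `"stairUp"`).
#' @param models Model list to modify (default [default_models()]).
#' @return Named list of [activity_model()]s.
#' @export
models_with_shared_accel <- function(source = "walk", target = "stairUp",
                                     models = default_models()) {
  stopifnot(source %in% names(models), target %in% names(models))
  for (field in c("accel_baseline", "accel_amp", "accel_phase", "freq")) {
    models[[target]][[field]] <- models[[source]][[field]]
  }
  models
}

#' Default training and test schedules
#'
#' One bout per activity, in a physically consistent order (a transition
#' sits between its two postures). Training uses 5-s bouts except the
#' momentary transitions (2 s); the test schedule uses longer bouts and a
#' different order so test movelets are not trivially the training windows.
#'
#' @return A tibble with columns `activity`, `duration` (seconds).
#' @export
training_schedule <- function() {
  tibble::tibble(
    activity = c("walk", "stairUp", "stairDown", "stand", "stand-to-sit",
                 "sit", "sit-to-stand"),
    duration = c(5, 5, 5, 5, 2, 5, 2)
  )
}

#' @rdname training_schedule
#' @export
test_schedule <- function() {
  tibble::tibble(
    activity = c("stand", "walk", "stairUp", "stairDown", "stand",
                 "stand-to-sit", "sit", "sit-to-stand", "stand"),
    duration = c(5, 10, 10, 10, 5, 2, 10, 2, 4)
  )
}

#' Simulate a paired accelerometer + gyroscope recording
#'
#' Generates one recording following a schedule of activity bouts, with
#' both sensors sampled at `hz` but the gyroscope grid shifted by
#' `gyro_offset` seconds — the two sensors of a real phone are not
#' synchronized, which is what makes interpolation necessary in the
#' joint-sensor mode. Ground-truth intervals exactly match the schedule.
#' Output is deterministic given `seed`.
#'
#' @param schedule Tibble/data frame with columns `activity`, `duration`
#'   (seconds); activities must exist in `models`.
#' @param models Named list of [activity_model()]s (default
#'   [default_models()]).
#' @param hz Sampling frequency of both sensors (default 10).
#' @param gyro_offset Shift of the gyroscope timestamp grid in seconds
#'   (default 0.03; must be in `[0, 1/hz)`).
#' @param seed Optional integer seed; when given, the caller's random state
#'   is left untouched.
#' @return List with elements `accel` and `gyro` ([sensor_stream()]s) and
#'   `intervals` (ground-truth tibble `label`, `start`, `end`).
#' @export
#' @examples
#' rec <- simulate_recording(training_schedule(), seed = 1)
#' rec$intervals
simulate_recording <- function(schedule, models = default_models(),
                               hz = 10, gyro_offset = 0.03, seed = NULL) {
  schedule <- tibble::as_tibble(schedule)
  if (nrow(schedule) == 0) {
    abort("schedule must be non-empty", class = "moveletr_format_error")
  }
  unknown <- setdiff(schedule$activity, names(models))
  if (length(unknown) > 0) {
    abort(paste0("schedule names unknown activity: ",
                 paste(unknown, collapse = ", ")),
          class = "moveletr_format_error")
  }
  if (any(schedule$duration <= 0)) {
    abort("durations must be positive", class = "moveletr_format_error")
  }
  if (gyro_offset < 0 || gyro_offset >= 1 / hz) {
    abort("gyro_offset must lie in [0, 1/hz)",
          class = "moveletr_format_error")
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old_seed)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  total <- sum(schedule$duration)
  starts <- cumsum(c(0, schedule$duration[-nrow(schedule)]))
  ends <- starts + schedule$duration
  accel_t <- seq(0, by = 1 / hz, length.out = round(total * hz))
  gyro_t <- gyro_offset + seq(0, by = 1 / hz,
                              length.out = floor((total - gyro_offset) * hz))
  make_stream <- function(times, sensor) {
    vals <- matrix(NA_real_, nrow = length(times), ncol = 3)
    for (i in seq_len(nrow(schedule))) {
      in_seg <- times >= starts[i] & times < ends[i]
      if (!any(in_seg)) next
      model <- models[[schedule$activity[i]]]
      vals[in_seg, ] <- activity_signal(model, times[in_seg] - starts[i],
                                        schedule$duration[i], sensor)
    }
    for (i in seq_len(nrow(schedule))) { # per-segment noise level
      in_seg <- times >= starts[i] & times < ends[i]
      if (!any(in_seg)) next
      sd <- models[[schedule$activity[i]]]$noise_sd[[sensor]]
      if (sd > 0) {
        vals[in_seg, ] <- vals[in_seg, ] +
          matrix(rnorm(sum(in_seg) * 3, sd = sd), ncol = 3)
      }
    }
    sensor_stream(
      tibble::tibble(time = times, x = vals[, 1], y = vals[, 2],
                     z = vals[, 3]),
      sensor_kind = if (sensor == "accel") "accelerometer" else "gyroscope",
      nominal_hz = hz
    )
  }
  list(
    accel = make_stream(accel_t, "accel"),
    gyro = make_stream(gyro_t, "gyro"),
    intervals = tibble::tibble(label = schedule$activity,
                               start = starts, end = ends)
  )
}

# Noise-free signal of one model at local times s (seconds since segment
# start), for one sensor; returns length(s) x 3 matrix.
activity_signal <- function(model, s, duration, sensor = c("accel", "gyro")) {
  sensor <- match.arg(sensor)
  n <- length(s)
  if (model$kind == "stationary") {
    base <- if (sensor == "accel") model$accel_baseline else model$gyro_baseline
    return(matrix(base, nrow = n, ncol = 3, byrow = TRUE))
  }
  if (model$kind == "periodic") {
    base <- if (sensor == "accel") model$accel_baseline else model$gyro_baseline
    amp <- if (sensor == "accel") model$accel_amp else model$gyro_amp
    phase <- if (sensor == "accel") model$accel_phase else model$gyro_phase
    out <- vapply(1:3, function(ax) {
      base[ax] + amp[ax] * sin(2 * pi * model$freq * s + phase[ax])
    }, numeric(n))
    return(matrix(out, nrow = n))
  }
  # transition: smoothstep blend of postures; gyro arc zero at both ends
  u <- pmin(pmax(s / duration, 0), 1)
  w <- 3 * u^2 - 2 * u^3
  if (sensor == "accel") {
    out <- vapply(1:3, function(ax) {
      model$accel_from[ax] + w * (model$accel_to[ax] - model$accel_from[ax])
    }, numeric(n))
    return(matrix(out, nrow = n))
  }
  arc <- sin(pi * u)^2
  wobble <- if (isTRUE(model$variable_start)) {
    1 + 0.6 * sin(2 * pi * 4 * s) * exp(-4 * u)
  } else {
    rep(1, n)
  }
  out <- vapply(1:3, function(ax) {
    model$gyro_arc_amp[ax] * arc * wobble
  }, numeric(n))
  matrix(out, nrow = n)
}
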