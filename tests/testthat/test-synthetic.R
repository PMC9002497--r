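test_that("default models encode the canonical posture signatures", {
  m <- default_models()
  expect_equal(m$stand$accel_baseline, c(-0.15, 0.98, 0.02))
  expect_equal(m$sit$accel_baseline, c(-0.73, 0.26, 0.64))
  # gyroscope identically zero for both stationary postures
  expect_equal(m$stand$gyro_baseline, c(0, 0, 0))
  expect_equal(m$sit$gyro_baseline, c(0, 0, 0))
  expect_setequal(names(m), activity_groups()$all)
  # pairwise distinguishable in at least one sensor: noiseless signals of
  # any two activities differ somewhere over a common 2-s bout
  quiet <- default_models(noise_sd = c(accel = 0, gyro = 0))
  sigs <- lapply(names(quiet), function(a) {
    rec <- simulate_recording(tibble::tibble(activity = a, duration = 2),
                              quiet, seed = 1, gyro_offset = 0)
    cbind(as.matrix(as.data.frame(rec$accel)[, -1]),
          as.matrix(as.data.frame(rec$gyro)[, -1]))
  })
  for (i in seq_along(sigs)) {
    for (j in seq_along(sigs)) {
      if (i < j) expect_gt(max(abs(sigs[[i]] - sigs[[j]])), 0.05)
    }
  }
})

test_that("noiseless stationary bouts are exactly constant", {
  quiet <- default_models(noise_sd = c(accel = 0, gyro = 0))
  rec <- simulate_recording(tibble::tibble(activity = "stand", duration = 5),
                            quiet, seed = 1)
  expect_true(all(rec$accel$x == -0.15))
  expect_true(all(rec$accel$y == 0.98))
  expect_true(all(rec$accel$z == 0.02))
  expect_true(all(rec$gyro$x == 0 & rec$gyro$y == 0 & rec$gyro$z == 0))
})

test_that("the same seed reproduces the recording bitwise", {
  a <- simulate_recording(training_schedule(), seed = 99)
  b <- simulate_recording(training_schedule(), seed = 99)
  expect_identical(as.data.frame(a$accel), as.data.frame(b$accel))
  expect_identical(as.data.frame(a$gyro), as.data.frame(b$gyro))
  expect_identical(a$intervals, b$intervals)
  c_ <- simulate_recording(training_schedule(), seed = 100)
  expect_false(identical(as.data.frame(a$accel), as.data.frame(c_$accel)))
})

test_that("seeded simulation leaves the caller's random state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_recording(training_schedule(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("noiseless periodic signals average to the baseline over whole cycles", {
  quiet <- default_models(noise_sd = c(accel = 0, gyro = 0))
  # walk: 2 Hz at 10 Hz sampling -> 5 samples per cycle; 5 s = 10 cycles
  rec <- simulate_recording(tibble::tibble(activity = "walk", duration = 5),
                            quiet, hz = 10, seed = 1)
  expect_equal(mean(rec$accel$x), quiet$walk$accel_baseline[1],
               tolerance = 1e-9)
  expect_equal(mean(rec$accel$y), quiet$walk$accel_baseline[2],
               tolerance = 1e-9)
  expect_equal(mean(rec$accel$z), quiet$walk$accel_baseline[3],
               tolerance = 1e-9)
})

test_that("ground-truth intervals exactly match the schedule and the gyro grid is offset", {
  sched <- training_schedule()
  rec <- simulate_recording(sched, seed = 3, gyro_offset = 0.03)
  expect_equal(rec$intervals$label, sched$activity)
  expect_equal(rec$intervals$end - rec$intervals$start, sched$duration)
  expect_equal(rec$intervals$start,
               cumsum(c(0, sched$duration[-nrow(sched)])))
  expect_equal(rec$accel$time[1], 0)
  expect_equal(rec$gyro$time[1], 0.03)
  # no gyro timestamp coincides with an accel timestamp
  expect_equal(length(intersect(rec$accel$time, rec$gyro$time)), 0)
})

test_that("transitions blend smoothly between the posture baselines", {
  quiet <- default_models(noise_sd = c(accel = 0, gyro = 0))
  sched <- tibble::tibble(activity = c("stand", "stand-to-sit", "sit"),
                          duration = c(2, 2, 2))
  rec <- simulate_recording(sched, quiet, seed = 1)
  acc <- rec$accel
  # endpoints of the transition equal the adjacent posture baselines
  at_start <- which.min(abs(acc$time - 2))
  expect_equal(acc$x[at_start], -0.15, tolerance = 1e-9)
  at_end <- max(which(acc$time < 4 - 1e-9))
  expect_equal(acc$x[at_end], -0.73, tolerance = 0.01)
  # monotone smooth blend in between, no overshoot
  mid <- acc$x[acc$time >= 2 - 1e-9 & acc$time < 4 - 1e-9]
  expect_true(all(mid <= -0.15 + 1e-12 & mid >= -0.73 - 1e-12))
  expect_true(all(diff(mid) <= 1e-12))
  # gyroscope arc starts and ends near zero
  gy <- rec$gyro
  arc <- gy$x[gy$time >= 2 & gy$time < 4]
  expect_lt(abs(arc[1]), 0.05)
  expect_lt(abs(arc[length(arc)]), 0.05)
  expect_gt(max(abs(arc)), 0.5)
})

test_that("unknown activities and bad schedules are rejected", {
  expect_error(
    simulate_recording(tibble::tibble(activity = "fly", duration = 5)),
    regexp = "fly", class = "moveletr_format_error"
  )
  expect_error(
    simulate_recording(tibble::tibble(activity = "walk", duration = -1)),
    class = "moveletr_format_error"
  )
  expect_error(
    simulate_recording(training_schedule(), gyro_offset = 0.2),
    class = "moveletr_format_error"
  )
})

test_that("models_with_shared_accel copies only the accelerometer side", {
  m <- models_with_shared_accel("walk", "stairUp")
  expect_equal(m$stairUp$accel_baseline, m$walk$accel_baseline)
  expect_equal(m$stairUp$accel_amp, m$walk$accel_amp)
  expect_equal(m$stairUp$freq, m$walk$freq)
  expect_false(isTRUE(all.equal(m$stairUp$gyro_amp, m$walk$gyro_amp)))
})
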