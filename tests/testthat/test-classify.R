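test_that("an exact dictionary copy matches with distance zero", {
  set.seed(19)
  segs <- list(walk = random_stream(20), stand = random_stream(20))
  dict <- build_dictionary(segs, 10)
  probe <- dict$movelets$values[[15]]
  res <- match_movelet(probe, dict)
  expect_equal(res$best_distance, 0)
  expect_equal(res$best_label, dict$movelets$activity[15])

  solo <- build_dictionary(list(only = random_stream(10)), 10)
  far <- random_movelet(3) + 100
  expect_equal(match_movelet(far, solo)$best_label, "only")
})

test_that("match_movelet agrees with the exhaustive-scan oracle", {
  set.seed(20)
  for (rep in 1:30) {
    n_act <- sample(2:4, 1)
    segs <- lapply(seq_len(n_act), function(i) random_stream(sample(10:25, 1)))
    names(segs) <- paste0("act", seq_len(n_act))
    dict <- build_dictionary(segs, 10)
    probe <- random_movelet(3)
    got <- match_movelet(probe, dict)
    want <- oracle_match(probe, dict)
    expect_identical(got$best_label, want$label)
    expect_equal(got$best_distance, want$distance, tolerance = 1e-12)
    expect_equal(got$best_index, want$index)
  }
})

test_that("classify_stream agrees with a naive window+vote reimplementation", {
  set.seed(21)
  for (rep in 1:12) {
    segs <- lapply(1:3, function(i) random_stream(sample(12:30, 1)))
    names(segs) <- c("a", "b", "c")
    dict <- build_dictionary(segs, 10)
    test <- random_stream(sample(15:40, 1))
    vw <- sample(c(1, 3, 10), 1)
    got <- classify_stream(test, dict, vote_width = vw)
    expect_identical(got$label, oracle_classify(test, dict, vw))
  }
})

test_that("self-classification returns the segment's own activity everywhere", {
  set.seed(22)
  segs <- constant_segments(n = 30)
  # add small noise so no two dictionary movelets are identical
  segs <- lapply(segs, function(s) {
    s$x <- s$x + rnorm(nrow(s), sd = 0.01)
    s$y <- s$y + rnorm(nrow(s), sd = 0.01)
    s$z <- s$z + rnorm(nrow(s), sd = 0.01)
    s
  })
  dict <- build_dictionary(segs, 10)
  for (act in names(segs)) {
    out <- classify_stream(segs[[act]], dict, vote_width = 10)
    labeled <- out$label[!is.na(out$label)]
    expect_true(all(labeled == act))
    expect_true(all(out$best_distance[!is.na(out$label)] == 0))
    expect_equal(sum(is.na(out$label)), 9) # final n-1 timestamps unlabeled
  }
})

test_that("majority vote picks the strict majority and documented tie rules", {
  vote <- moveletr:::majority_label
  order_ <- c("walk", "stairUp", "sit")
  # strict majority: walk x6 vs stairUp x4
  labels <- c(rep("walk", 6), rep("stairUp", 4))
  expect_equal(vote(labels, rep(1, 10), order_), "walk")
  # count tie: winner is the label with the closest contributing movelet
  labels <- c(rep("walk", 5), rep("stairUp", 5))
  dists <- c(rep(0.9, 5), 0.1, rep(0.9, 4))
  expect_equal(vote(labels, dists, order_), "stairUp")
  # full tie: dictionary activity order decides
  expect_equal(vote(c("sit", "walk"), c(0.5, 0.5), order_), "walk")
})

test_that("with vote_width = 1 the vote is the identity on raw matches", {
  set.seed(23)
  segs <- lapply(1:2, function(i) random_stream(15))
  names(segs) <- c("a", "b")
  dict <- build_dictionary(segs, 10)
  test <- random_stream(30)
  out <- classify_stream(test, dict, vote_width = 1)
  matches <- attr(out, "matches")
  expect_identical(out$label[seq_len(nrow(matches))], matches$best_label)
})

test_that("label mapping picks the nearest source timestamp, earlier on ties", {
  src <- label_series(c(0, 1, 2), c("a", "b", "c"))
  expect_identical(map_labels_to_timestamps(src, c(0, 1, 2))$label,
                   c("a", "b", "c"))
  # midway: tie toward the earlier timestamp
  expect_identical(map_labels_to_timestamps(src, 0.5)$label, "a")
  expect_identical(map_labels_to_timestamps(src, 1.5)$label, "b")
  # outside the span: clamp to nearest end
  expect_identical(map_labels_to_timestamps(src, c(-5, 7))$label,
                   c("a", "c"))

  set.seed(24)
  for (rep in 1:15) {
    st <- sort(runif(sample(2:20, 1), 0, 10))
    st <- st[!duplicated(st)]
    src <- label_series(st, sample(letters[1:4], length(st), replace = TRUE))
    targets <- sort(runif(25, -1, 11))
    got <- map_labels_to_timestamps(src, targets)
    expected <- vapply(targets, function(t) { # linear-scan oracle
      best <- 1
      for (i in seq_along(st)) {
        if (abs(st[i] - t) < abs(st[best] - t)) best <- i
      }
      src$label[best]
    }, character(1))
    expect_identical(got$label, expected)
  }
})

test_that("run_method demands the streams its mode needs", {
  set.seed(25)
  rec <- simulate_recording(training_schedule(), seed = 1)
  expect_error(
    run_method(NULL, rec$gyro, rec$intervals, NULL, rec$gyro, "accel_only"),
    class = "moveletr_configuration_error"
  )
  expect_error(
    run_method(rec$accel, NULL, rec$intervals, rec$accel, NULL, "joint"),
    class = "moveletr_configuration_error"
  )
})

test_that("all three modes label exactly the accelerometer timestamp grid", {
  train <- simulate_recording(training_schedule(), seed = 31)
  test <- simulate_recording(test_schedule(), seed = 32)
  for (mode in c("accel_only", "gyro_only", "joint")) {
    out <- run_method(train$accel, train$gyro, train$intervals,
                      test$accel, test$gyro, mode = mode)
    if (mode == "joint") {
      joint <- build_joint_stream(test$accel, test$gyro)
      expect_identical(out$time, joint$time)
      expect_true(all(out$time %in% test$accel$time))
    } else {
      expect_identical(out$time, test$accel$time)
    }
  }
})

test_that("separable constant signatures give perfect accel-only labels", {
  # unique constant accelerometer signature per activity, noiseless test;
  # single-activity test bouts so no movelet straddles an activity change
  models <- default_models(noise_sd = c(accel = 0, gyro = 0))
  sched <- tibble::tibble(activity = c("stand", "sit"), duration = c(5, 5))
  train <- simulate_recording(sched, models, seed = 1)
  for (act in c("stand", "sit")) {
    bout <- simulate_recording(tibble::tibble(activity = act, duration = 5),
                               models, seed = 2)
    out <- run_method(train$accel, train$gyro, train$intervals,
                      bout$accel, bout$gyro, mode = "accel_only")
    expect_true(all(out$label[!is.na(out$label)] == act))
  }
})
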