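#' Match one test movelet against a dictionary
#'
#' Finds the dictionary movelet with the smallest discrepancy from the test
#' movelet (exhaustive scan — dictionaries are small, on the order of 41
#' movelets per activity). Ties are broken deterministically: smallest
#' distance, then earliest activity in the dictionary's declared order,
#' then lowest movelet index.
#'
#' @param test A movelet value matrix (channels x samples) or one-row
#'   movelet tibble.
#' @param dictionary A [build_dictionary()] result.
#' @param weights Optional per-channel weights (see
#'   [movelet_discrepancy()]).
#' @return A one-row tibble: `best_label`, `best_distance`,
#'   `best_activity`, `best_index`.
#' @export
match_movelet <- function(test, dictionary, weights = NULL) {
  stopifnot(is_movelet_dictionary(dictionary))
  d <- discrepancy_matrix(list(movelet_values(test)), dictionary$movelets$values,
                          weights = weights)
  best <- argmin_matches(d, dictionary)
  best
}

# Row-wise argmin over a discrepancy matrix, honoring the tie-break order.
# Dictionary movelets are stored sorted by (declared activity order, index),
# so the first minimum is the tie-break winner.
argmin_matches <- function(d, dictionary) {
  mv <- dictionary$movelets
  stopifnot(all(order(match(mv$activity, dictionary$activities),
                      mv$index) == seq_len(nrow(mv))))
  idx <- apply(d, 1, which.min)
  tibble::tibble(
    best_label = mv$activity[idx],
    best_distance = d[cbind(seq_len(nrow(d)), idx)],
    best_activity = mv$activity[idx],
    best_index = mv$index[idx]
  )
}

#' Classify a test stream against a dictionary
#'
#' Extracts sliding-window test movelets, matches each to its nearest
#' dictionary movelet, and smooths with a majority vote: the label at a
#' timestamp is the modal nearest-dictionary label among the movelet
#' beginning there and the following `vote_width - 1` movelets (default 10
#' voters, i.e. the movelet at `t` plus the subsequent nine). Near the end
#' of the series the window is clipped to the available movelets rather
#' than dropped, so every movelet start time receives a label. The final
#' `window_samples - 1` timestamps start no movelet and receive `NA`.
#'
#' Vote ties are broken toward the modal label whose contributing movelet
#' in the window has the smallest match distance, then by the dictionary's
#' declared activity order.
#'
#' @param test A [sensor_stream()] or [joint_stream()]; channel count must
#'   match the dictionary.
#' @param dictionary A `movelet_dictionary`.
#' @param vote_width Positive integer number of movelets per vote
#'   (default 10); `1` disables smoothing.
#' @param weights Optional per-channel weights.
#' @return A [label_series()] on the full test timestamp grid with columns
#'   `time`, `label`, `best_distance` (the voted label's smallest
#'   contributing match distance; `NA` on unlabeled timestamps). The raw
#'   per-movelet matches are attached as attribute `matches` (tibble:
#'   `start_time`, `best_label`, `best_distance`, `best_index`).
#' @export
classify_stream <- function(test, dictionary, vote_width = 10,
                            weights = NULL) {
  stopifnot(is_movelet_dictionary(dictionary))
  vote_width <- as.integer(vote_width)
  if (vote_width < 1) {
    abort("vote_width must be >= 1", class = "moveletr_format_error")
  }
  test_mv <- extract_movelets(test, dictionary$window_samples)
  d <- discrepancy_matrix(test_mv$values, dictionary$movelets$values,
                          weights = weights)
  matches <- argmin_matches(d, dictionary)
  tie_count <- sum(vapply(seq_len(nrow(d)), function(i) {
    sum(d[i, ] == matches$best_distance[i]) > 1
  }, logical(1)))
  matches <- tibble::tibble(start_time = test_mv$start_time,
                            best_label = matches$best_label,
                            best_distance = matches$best_distance,
                            best_index = matches$best_index)
  m <- nrow(matches)
  voted <- character(m)
  voted_dist <- numeric(m)
  for (i in seq_len(m)) {
    win <- i:min(i + vote_width - 1L, m)
    winner <- majority_label(matches$best_label[win],
                             matches$best_distance[win],
                             dictionary$activities)
    voted[i] <- winner
    voted_dist[i] <- min(matches$best_distance[win][matches$best_label[win] == winner])
  }
  n_total <- nrow(test)
  label <- c(voted, rep(NA_character_, n_total - m))
  dist <- c(voted_dist, rep(NA_real_, n_total - m))
  out <- label_series(test$time, label, best_distance = dist)
  attr(out, "matches") <- matches
  attr(out, "tie_count") <- tie_count
  out
}

# Modal label of one vote window. Ties: smallest contributing distance,
# then declared activity order.
majority_label <- function(labels, distances, activity_order) {
  counts <- table(labels)
  modal <- names(counts)[counts == max(counts)]
  if (length(modal) > 1) {
    best_dist <- vapply(modal, function(a) min(distances[labels == a]), 0)
    modal <- modal[best_dist == min(best_dist)]
    if (length(modal) > 1) {
      modal <- modal[order(match(modal, activity_order))][1]
    }
  }
  modal[1]
}

#' Map a label series onto new timestamps by nearest neighbor
#'
#' Each target timestamp receives the label of the nearest source timestamp
#' (smallest absolute time difference); a target exactly midway between two
#' source timestamps takes the earlier one's label. Used to place
#' gyroscope-only classifications (made on the original gyroscope timestamp
#' grid) onto the accelerometer timestamps, so all three analysis modes are
#' compared on the same grid.
#'
#' @param source A [label_series()].
#' @param target_timestamps Strictly increasing numeric vector of seconds.
#' @return A [label_series()] on `target_timestamps`.
#' @export
map_labels_to_timestamps <- function(source, target_timestamps) {
  if (nrow(source) == 0) {
    abort("source label series is empty", class = "moveletr_empty_input_error")
  }
  if (length(target_timestamps) > 1 && any(diff(target_timestamps) <= 0)) {
    abort("target timestamps must be strictly increasing",
          class = "moveletr_format_error")
  }
  st <- source$time
  lower <- findInterval(target_timestamps, st)
  idx <- integer(length(target_timestamps))
  for (k in seq_along(target_timestamps)) {
    i <- lower[k]
    if (i == 0) {
      idx[k] <- 1L
    } else if (i == length(st)) {
      idx[k] <- i
    } else {
      # tie (equal distance) goes to the earlier source timestamp
      d_lo <- target_timestamps[k] - st[i]
      d_hi <- st[i + 1] - target_timestamps[k]
      idx[k] <- if (d_lo <= d_hi) i else i + 1L
    }
  }
  label_series(target_timestamps, source$label[idx])
}

#' Run one full analysis mode end to end
#'
#' Builds the dictionary from a labeled training recording, classifies the
#' test recording, and returns labels on the test accelerometer timestamp
#' grid — the shared grid on which the three modes are compared:
#'
#' * `"accel_only"`: dictionary and test movelets from the accelerometer
#'   stream alone (3-channel DS metric).
#' * `"gyro_only"`: dictionary and test movelets from the original,
#'   uninterpolated gyroscope stream; the resulting per-gyroscope-timestamp
#'   labels are mapped to the accelerometer timestamps via the closest
#'   gyroscope timestamp.
#' * `"joint"`: the gyroscope is linearly interpolated to the accelerometer
#'   timestamps for training and test alike, and six-channel movelets are
#'   matched under the DJ metric.
#'
#' @param train_accel,train_gyro Training [sensor_stream()]s (either may be
#'   `NULL` if the mode does not use it).
#' @param train_intervals Training annotations (`label`, `start`, `end`).
#' @param test_accel,test_gyro Test streams.
#' @param mode `"accel_only"`, `"gyro_only"` or `"joint"`.
#' @param window_samples Movelet length in samples (default 10, i.e. 1 s at
#'   10 Hz).
#' @param vote_width Majority-vote width in movelets (default 10).
#' @param train_seconds Per-activity training cap in seconds (default 5).
#' @param weights Optional per-channel weights.
#' @return A [label_series()] on the test accelerometer timestamps (after
#'   any boundary drops from interpolation in joint mode), with the fitted
#'   dictionary attached as attribute `dictionary`.
#' @export
run_method <- function(train_accel, train_gyro, train_intervals,
                       test_accel, test_gyro,
                       mode = c("accel_only", "gyro_only", "joint"),
                       window_samples = 10, vote_width = 10,
                       train_seconds = 5, weights = NULL) {
  mode <- match.arg(mode)
  need <- switch(mode,
                 accel_only = c(accel = TRUE, gyro = FALSE),
                 gyro_only = c(accel = FALSE, gyro = TRUE),
                 joint = c(accel = TRUE, gyro = TRUE))
  if (need[["accel"]] && (is.null(train_accel) || is.null(test_accel))) {
    abort(paste0("mode '", mode, "' requires accelerometer streams"),
          class = "moveletr_configuration_error")
  }
  if (need[["gyro"]] && (is.null(train_gyro) || is.null(test_gyro))) {
    abort(paste0("mode '", mode, "' requires gyroscope streams"),
          class = "moveletr_configuration_error")
  }
  if (mode == "gyro_only" && is.null(test_accel)) {
    abort("gyro_only mode requires test accelerometer timestamps to map onto",
          class = "moveletr_configuration_error")
  }
  if (mode == "accel_only") {
    dict <- dictionary_from_annotations(train_accel, train_intervals,
                                        window_samples, train_seconds)
    out <- classify_stream(test_accel, dict, vote_width, weights)
  } else if (mode == "gyro_only") {
    dict <- dictionary_from_annotations(train_gyro, train_intervals,
                                        window_samples, train_seconds)
    gyro_labels <- classify_stream(test_gyro, dict, vote_width, weights)
    out <- map_labels_to_timestamps(gyro_labels, test_accel$time)
    attr(out, "matches") <- attr(gyro_labels, "matches")
    attr(out, "tie_count") <- attr(gyro_labels, "tie_count")
  } else {
    train_joint <- build_joint_stream(train_accel, train_gyro)
    test_joint <- build_joint_stream(test_accel, test_gyro)
    dict <- dictionary_from_annotations(train_joint, train_intervals,
                                        window_samples, train_seconds)
    out <- classify_stream(test_joint, dict, vote_width, weights)
  }
  attr(out, "dictionary") <- dict
  out
}
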