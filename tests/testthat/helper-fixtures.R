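# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate correctness.

random_stream <- function(n, hz = 10, kind = "accelerometer", t0 = 0) {
  sensor_stream(
    tibble::tibble(time = t0 + (seq_len(n) - 1) / hz,
                   x = rnorm(n), y = rnorm(n), z = rnorm(n)),
    sensor_kind = kind, nominal_hz = hz
  )
}

random_movelet <- function(n_channels = 3, n_samples = 10) {
  ch <- if (n_channels == 3) c("x", "y", "z") else
    c("xa", "ya", "za", "xg", "yg", "zg")
  matrix(rnorm(n_channels * n_samples), nrow = n_channels,
         dimnames = list(ch, NULL))
}

# Oracle: discrepancy via explicit per-axis loops over samples.
oracle_discrepancy <- function(m1, m2) {
  total <- 0
  for (ch in seq_len(nrow(m1))) {
    ss <- 0
    for (k in seq_len(ncol(m1))) ss <- ss + (m1[ch, k] - m2[ch, k])^2
    total <- total + sqrt(ss)
  }
  unname(total / nrow(m1))
}

# Oracle: exhaustive nearest-dictionary scan in declared storage order.
oracle_match <- function(test_values, dictionary) {
  best_d <- Inf
  best_row <- NA_integer_
  mv <- dictionary$movelets
  for (j in seq_len(nrow(mv))) {
    d <- oracle_discrepancy(test_values, mv$values[[j]])
    if (d < best_d) {
      best_d <- d
      best_row <- j
    }
  }
  list(label = mv$activity[best_row], distance = best_d,
       index = mv$index[best_row])
}

# Oracle: full window + majority vote reimplementation.
oracle_classify <- function(test, dictionary, vote_width) {
  n <- nrow(test)
  ws <- dictionary$window_samples
  mat <- as.matrix(as.data.frame(test)[, setdiff(names(test), "time")])
  m <- n - ws + 1
  labels <- character(m)
  dists <- numeric(m)
  for (i in seq_len(m)) {
    res <- oracle_match(t(mat[i:(i + ws - 1), , drop = FALSE]), dictionary)
    labels[i] <- res$label
    dists[i] <- res$distance
  }
  voted <- character(m)
  for (i in seq_len(m)) {
    win <- i:min(i + vote_width - 1, m)
    tab <- table(labels[win])
    modal <- names(tab)[tab == max(tab)]
    if (length(modal) > 1) {
      md <- vapply(modal, function(a) min(dists[win][labels[win] == a]), 0)
      modal <- modal[md == min(md)]
      if (length(modal) > 1) {
        modal <- modal[order(match(modal, dictionary$activities))][1]
      }
    }
    voted[i] <- modal[1]
  }
  c(voted, rep(NA_character_, n - m))
}

# A small labeled training set: one segment per activity with clearly
# separated constant accelerometer levels (trivially separable).
constant_segments <- function(levels = list(a = c(0, 0, 1), b = c(1, 0, 0),
                                            c = c(0, 1, 0)),
                              n = 20, hz = 10) {
  segs <- lapply(levels, function(v) {
    sensor_stream(
      tibble::tibble(time = (seq_len(n) - 1) / hz,
                     x = rep(v[1], n), y = rep(v[2], n), z = rep(v[3], n)),
      nominal_hz = hz
    )
  })
  names(segs) <- names(levels)
  segs
}
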