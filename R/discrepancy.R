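#' Per-axis Euclidean distance
#'
#' The building block of the movelet discrepancy metrics: the ordinary
#' Euclidean distance `sqrt(sum((a - b)^2))` between the two movelets'
#' time series on one axis.
#'
#' @param a,b Equal-length numeric vectors.
#' @return A non-negative scalar.
#' @export
#' @examples
#' axis_distance(c(0, 0), c(3, 4)) # 5
axis_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort("axis vectors must have equal length",
          class = "moveletr_dimension_error")
  }
  sqrt(sum((a - b)^2))
}

#' Movelet discrepancy (DS / DJ)
#'
#' The discrepancy between two movelets is the per-channel Euclidean
#' distance averaged over channels. With 3 channels (one tri-axial sensor)
#' this is the single-sensor metric DS; with 6 channels (accelerometer +
#' interpolated gyroscope) it is the joint-sensor metric DJ — one formula,
#' the divisor is the channel count. No unit normalization is applied
#' before averaging: accelerometer distances (g) and gyroscope distances
#' (rad/s) enter on their raw scales.
#'
#' @param m1,m2 Movelet value matrices (channels x samples) with matching
#'   dimensions, as stored by [extract_movelets()].
#' @param weights Optional per-channel weight vector; defaults to uniform
#'   `1/D` averaging (must be non-negative and sum to a positive value;
#'   normalized internally).
#' @return A non-negative scalar.
#' @export
movelet_discrepancy <- function(m1, m2, weights = NULL) {
  m1 <- movelet_values(m1)
  m2 <- movelet_values(m2)
  if (!all(dim(m1) == dim(m2))) {
    abort(sprintf("movelet dimensions differ: %dx%d vs %dx%d",
                  nrow(m1), ncol(m1), nrow(m2), ncol(m2)),
          class = "moveletr_dimension_error")
  }
  w <- check_weights(weights, nrow(m1))
  sum(w * sqrt(rowSums((m1 - m2)^2)))
}

# Accept a bare matrix or a one-row movelet tibble.
movelet_values <- function(m) {
  if (is.matrix(m)) return(m)
  if (is.data.frame(m) && "values" %in% names(m) && nrow(m) == 1) {
    return(m$values[[1]])
  }
  if (is.list(m) && length(m) == 1 && is.matrix(m[[1]])) return(m[[1]])
  abort("expected a channels-by-samples matrix or a one-row movelet tibble",
        class = "moveletr_format_error")
}

check_weights <- function(weights, n_channels) {
  if (is.null(weights)) return(rep(1 / n_channels, n_channels))
  if (length(weights) != n_channels || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative, positive-sum, one per channel",
          class = "moveletr_format_error")
  }
  weights / sum(weights)
}

# All pairwise discrepancies between two sets of movelets, vectorized over
# test movelets: exact per-pair differences (no inner-product expansion, so
# an identical pair yields exactly zero). Rows = test movelets, columns =
# dictionary movelets.
discrepancy_matrix <- function(test_values, dict_values, weights = NULL) {
  d_channels <- nrow(dict_values[[1]])
  n_samples <- ncol(dict_values[[1]])
  if (nrow(test_values[[1]]) != d_channels ||
      ncol(test_values[[1]]) != n_samples) {
    abort("test and dictionary movelet dimensions differ",
          class = "moveletr_dimension_error")
  }
  w <- check_weights(weights, d_channels)
  # per-channel test matrices (n_samples x n_test), once
  tms <- lapply(seq_len(d_channels), function(ch) {
    vapply(test_values, function(v) v[ch, ], numeric(n_samples))
  })
  if (n_samples == 1) tms <- lapply(tms, function(m) matrix(m, nrow = 1))
  out <- matrix(0, nrow = length(test_values), ncol = length(dict_values))
  for (j in seq_along(dict_values)) {
    dj <- dict_values[[j]]
    acc <- 0
    for (ch in seq_len(d_channels)) {
      acc <- acc + w[ch] * sqrt(colSums((tms[[ch]] - dj[ch, ])^2))
    }
    out[, j] <- acc
  }
  out
}
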