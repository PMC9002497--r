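#' Column-normalized confusion matrix
#'
#' Tallies predicted vs. ground-truth labels on a shared timestamp grid.
#' Columns are ground-truth activities and each nonempty column of the
#' percentage matrix sums to 100, so a column shows how one true activity's
#' time was distributed across predicted labels. Timestamps whose truth
#' label is `NA` (unlabeled) or in `exclude` are removed before tallying;
#' predictions of an excluded label against an included truth still count
#' as errors in that truth column. Timestamps where the prediction is `NA`
#' (e.g. stream-end samples that start no movelet) are also dropped, since
#' no classification was made there.
#'
#' @param truth,predicted [label_series()] objects on identical timestamp
#'   grids.
#' @param exclude Character vector of truth labels to exclude (e.g. an
#'   out-of-dictionary activity such as `"revolving door"`).
#' @param activities Optional character vector fixing row/column order;
#'   defaults to truth-label order of first appearance, then any extra
#'   predicted labels.
#' @return An object of class `movelet_confusion`: list with `counts` and
#'   `percent` matrices (rows = predicted, columns = truth; empty truth
#'   columns are absent, never zero-division artifacts), `n` (tallied
#'   timestamps), `truth_labels`, `predicted_labels`.
#' @export
confusion_matrix <- function(truth, predicted, exclude = character(),
                             activities = NULL) {
  if (nrow(truth) != nrow(predicted) ||
      !isTRUE(all.equal(truth$time, predicted$time))) {
    abort("truth and predicted label series must share one timestamp grid",
          class = "moveletr_alignment_error")
  }
  keep <- !is.na(truth$label) & !(truth$label %in% exclude) &
    !is.na(predicted$label)
  t_lab <- truth$label[keep]
  p_lab <- predicted$label[keep]
  levels_all <- activities %||% unique(c(unique(t_lab), unique(p_lab)))
  counts <- table(
    predicted = factor(p_lab, levels = levels_all),
    truth = factor(t_lab, levels = levels_all)
  )
  counts <- matrix(as.integer(counts), nrow = length(levels_all),
                   dimnames = list(predicted = levels_all,
                                   truth = levels_all))
  col_totals <- colSums(counts)
  nonempty <- col_totals > 0
  counts <- counts[, nonempty, drop = FALSE]
  percent <- sweep(counts, 2, col_totals[nonempty], "/") * 100
  structure(
    list(counts = counts, percent = percent, n = sum(counts),
         truth_labels = colnames(counts),
         predicted_labels = rownames(counts)),
    class = "movelet_confusion"
  )
}

#' Default activity groupings
#'
#' The groupings used to summarize accuracy: all seven dictionary
#' activities; vigorous = walking and stair climbing; stationary = sitting
#' and standing; transition = the two postural transitions.
#'
#' @return Named list of character vectors.
#' @export
activity_groups <- function() {
  list(
    all = c("walk", "stand", "stairUp", "stairDown", "sit",
            "sit-to-stand", "stand-to-sit"),
    vigorous = c("walk", "stairUp", "stairDown"),
    stationary = c("stand", "sit"),
    transition = c("stand-to-sit", "sit-to-stand")
  )
}

#' Average per-group accuracy from a confusion matrix
#'
#' The accuracy of one activity is its diagonal entry of the
#' column-normalized confusion matrix (percent of that activity's time
#' classified correctly). A group's average accuracy is the unweighted mean
#' of its activities' diagonal entries — not weighted by how long each
#' activity was performed.
#'
#' @param cm A [confusion_matrix()] result.
#' @param groups Named list of activity vectors (default
#'   [activity_groups()]). Groups with no member present as a truth column
#'   are dropped; a group partially present errors, naming the absent
#'   activity.
#' @return A tibble with columns `group`, `accuracy` (percent),
#'   `n_activities`.
#' @export
group_accuracy <- function(cm, groups = activity_groups()) {
  stopifnot(inherits(cm, "movelet_confusion"))
  diag_pct <- diagonal_accuracy(cm)
  rows <- purrr::imap(groups, function(members, name) {
    present <- members %in% cm$truth_labels
    if (!any(present)) return(NULL)
    if (!all(present)) {
      abort(paste0("group '", name, "' references truth column(s) absent ",
                   "from the confusion matrix: ",
                   paste(members[!present], collapse = ", ")),
            class = "moveletr_format_error")
    }
    tibble::tibble(group = name,
                   accuracy = mean(diag_pct[members]),
                   n_activities = length(members))
  })
  dplyr::bind_rows(rows)
}

#' Per-activity diagonal accuracies
#'
#' @param cm A [confusion_matrix()] result.
#' @return Named numeric vector: percent of each truth activity's samples
#'   predicted as itself.
#' @export
diagonal_accuracy <- function(cm) {
  stopifnot(inherits(cm, "movelet_confusion"))
  vapply(cm$truth_labels, function(a) {
    if (a %in% cm$predicted_labels) cm$percent[a, a] else 0
  }, 0)
}

#' @export
print.movelet_confusion <- function(x, digits = 1, ...) {
  cat(sprintf("<movelet_confusion: %d timestamps, %d truth activities>\n",
              x$n, length(x$truth_labels)))
  cat("column-normalized percent (columns sum to 100):\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Tidy a confusion matrix
#'
#' @param x A `movelet_confusion`.
#' @param ... Unused.
#' @return `tidy()`: long tibble (`truth`, `predicted`, `count`,
#'   `percent`). `glance()`: one row with `n`, `n_truth_activities` and
#'   `overall_accuracy` (percent of tallied timestamps on the diagonal).
#' @export
tidy.movelet_confusion <- function(x, ...) {
  long <- as.data.frame.table(x$counts, responseName = "count",
                              stringsAsFactors = FALSE)
  long$percent <- as.vector(x$percent)
  tibble::as_tibble(long[, c("truth", "predicted", "count", "percent")])
}

#' @rdname tidy.movelet_confusion
#' @export
glance.movelet_confusion <- function(x, ...) {
  on_diag <- sum(vapply(x$truth_labels, function(a) {
    if (a %in% x$predicted_labels) x$counts[a, a] else 0L
  }, 0L))
  tibble::tibble(
    n = x$n,
    n_truth_activities = length(x$truth_labels),
    overall_accuracy = 100 * on_diag / x$n
  )
}

#' Write confusion-matrix output as CSV
#'
#' Writes the long (tidy) form: `truth`, `predicted`, `count`, `percent`.
#'
#' @param cm A `movelet_confusion`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  readr::write_csv(tidy(cm), path)
  invisible(path)
}
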