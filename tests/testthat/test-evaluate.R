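test_that("perfect prediction gives an identity percent matrix", {
  ts <- (0:29) / 10
  lab <- rep(c("walk", "sit", "stand"), each = 10)
  truth <- label_series(ts, lab)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm$percent)), rep(100, 3))
  expect_equal(sum(cm$counts), 30)
  expect_equal(glance(cm)$overall_accuracy, 100)
})

test_that("column normalization: a half-right column splits 50/50", {
  ts <- (0:19) / 10
  truth <- label_series(ts, rep("walk", 20))
  pred <- label_series(ts, rep(c("walk", "stand"), each = 10))
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$percent["walk", "walk"], 50)
  expect_equal(cm$percent["stand", "walk"], 50)
  expect_equal(colnames(cm$counts), "walk") # empty truth columns absent
})

test_that("confusion tallies match a loop oracle and columns sum to 100", {
  set.seed(26)
  acts <- c("a", "b", "c", "d")
  for (rep in 1:15) {
    n <- sample(20:80, 1)
    ts <- seq_len(n) / 10
    truth <- label_series(ts, sample(acts, n, replace = TRUE))
    pred <- label_series(ts, sample(acts, n, replace = TRUE))
    cm <- confusion_matrix(truth, pred, activities = acts)
    # loop oracle
    for (tr in colnames(cm$counts)) {
      for (pr in rownames(cm$counts)) {
        want <- 0
        for (i in seq_len(n)) {
          if (truth$label[i] == tr && pred$label[i] == pr) want <- want + 1
        }
        expect_equal(cm$counts[pr, tr], want)
      }
    }
    expect_true(all(abs(colSums(cm$percent) - 100) < 1e-9))
  }
})

test_that("excluded and unlabeled truth samples are removed; excluded predictions still count", {
  ts <- (0:9) / 10
  truth <- label_series(ts, c(rep("walk", 4), rep("door", 3),
                              rep(NA_character_, 3)))
  pred <- label_series(ts, c("walk", "walk", "door", "walk",
                             rep("walk", 3), rep("walk", 3)))
  cm <- confusion_matrix(truth, pred, exclude = "door")
  expect_equal(colnames(cm$counts), "walk")
  expect_equal(sum(cm$counts), 4) # only labeled, non-excluded truth
  # the prediction of the excluded label against included truth is an error
  expect_equal(cm$counts["door", "walk"], 1L)
  expect_equal(cm$percent["walk", "walk"], 75)
})

test_that("mismatched timestamp grids are an alignment error", {
  a <- label_series(c(0, 1), c("x", "y"))
  b <- label_series(c(0, 1.5), c("x", "y"))
  expect_error(confusion_matrix(a, b), class = "moveletr_alignment_error")
})

test_that("group accuracies are unweighted diagonal means", {
  ts <- seq_len(70) / 10
  acts <- activity_groups()$all
  truth <- label_series(ts, rep(acts, each = 10))
  cm_perfect <- confusion_matrix(truth, truth, activities = acts)
  ga <- group_accuracy(cm_perfect)
  expect_equal(ga$accuracy, rep(100, 4))

  # engineered diagonals: walk 80, stairUp 90, stairDown 70 -> vigorous 80
  pred_lab <- truth$label
  flip <- function(act, n_wrong, to) {
    idx <- which(truth$label == act)[seq_len(n_wrong)]
    pred_lab[idx] <<- to
  }
  flip("walk", 2, "stand")     # 80%
  flip("stairUp", 1, "stand")  # 90%
  flip("stairDown", 3, "stand") # 70%
  cm <- confusion_matrix(truth, label_series(ts, pred_lab),
                         activities = acts)
  ga <- group_accuracy(cm)
  expect_equal(ga$accuracy[ga$group == "vigorous"], 80)
  expect_equal(ga$accuracy[ga$group == "stationary"], 100)
  # "all" is the mean over the seven dictionary activities' diagonals
  expect_equal(ga$accuracy[ga$group == "all"],
               mean(diagonal_accuracy(cm)[acts]))

  # random matrices vs direct mean oracle
  set.seed(27)
  for (rep in 1:10) {
    pred <- label_series(ts, sample(acts, 70, replace = TRUE))
    cm_r <- confusion_matrix(truth, pred, activities = acts)
    ga_r <- group_accuracy(cm_r)
    for (g in ga_r$group) {
      members <- activity_groups()[[g]]
      want <- mean(vapply(members, function(a) cm_r$percent[a, a], 0))
      expect_equal(ga_r$accuracy[ga_r$group == g], want)
    }
  }
})

test_that("a group naming an absent truth column errors with its name", {
  ts <- (0:9) / 10
  truth <- label_series(ts, rep("walk", 10))
  cm <- confusion_matrix(truth, truth)
  expect_error(
    group_accuracy(cm, list(vigorous = c("walk", "stairUp"))),
    regexp = "stairUp", class = "moveletr_format_error"
  )
  # groups with no member present are silently dropped
  ga <- group_accuracy(cm, list(solo = "walk", other = c("sit", "stand")))
  expect_equal(ga$group, "solo")
})

test_that("tidy/glance/write_confusion expose the tallies faithfully", {
  ts <- (0:19) / 10
  truth <- label_series(ts, rep(c("walk", "sit"), each = 10))
  pred <- label_series(ts, c(rep("walk", 8), "sit", "sit", rep("sit", 10)))
  cm <- confusion_matrix(truth, pred)
  td <- tidy(cm)
  expect_equal(sum(td$count), 20)
  expect_equal(td$count[td$truth == "walk" & td$predicted == "sit"], 2L)
  expect_equal(glance(cm)$overall_accuracy, 90)
  p <- withr::local_tempfile(fileext = ".csv")
  write_confusion(cm, p)
  back <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(sum(back$count), 20)
})
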