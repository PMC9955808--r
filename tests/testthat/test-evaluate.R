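test_that("confusion matrix tallies true rows against predicted columns", {
  lv <- c("0", "1", "2")
  cm <- confusion_matrix(c("0", "1", "2"), c("0", "1", "2"), lv)
  expect_equal(unname(diag(cm)), c(1, 1, 1))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  cm2 <- confusion_matrix(c("0", "1", "1"), c("0", "0", "1"), lv)
  expect_equal(cm2["1", "0"], 1L)
  expect_error(confusion_matrix("0", "7", lv), "outside")

  set.seed(10)
  yt <- sample(mas_levels(), 200, replace = TRUE)
  yp <- sample(mas_levels(), 200, replace = TRUE)
  cm <- confusion_matrix(yt, yp)
  for (a in mas_levels()) for (b in mas_levels()) {
    expect_identical(cm[a, b], sum(yt == a & yp == b))
  }
  rn <- confusion_matrix(yt, yp, normalize = TRUE)
  expect_equal(unname(rowSums(rn)), rep(1, 6))
})

test_that("precision/recall/F follow their defining ratios", {
  # a printed cascade row: P = 1.00, R = 0.89 gives F = 0.94 at 2 dp
  cm <- matrix(c(8, 1, 0, 5), 2, byrow = TRUE,
               dimnames = list(c("1", "x"), c("1", "x")))
  pr <- precision_recall_f(cm)
  expect_equal(round(pr$precision[1], 2), 1.00)
  expect_equal(round(pr$recall[1], 2), 0.89)
  expect_equal(round(pr$f[1], 2), 0.94)
  # harmonic-mean identity when P = R
  cm2 <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pr2 <- precision_recall_f(cm2)
  expect_equal(pr2$f, pr2$precision)
  # absent, never-predicted class: all zero with flag
  cm3 <- matrix(c(2, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pr3 <- precision_recall_f(cm3)
  expect_equal(unlist(pr3[2, c("precision", "recall", "f")],
                      use.names = FALSE), c(0, 0, 0))
  expect_true(pr3$zero_division[2])
})

test_that("accuracy is the confusion trace over the total", {
  cm <- diag(c(4, 5, 6))
  expect_equal(accuracy(cm), 1)
  expect_equal(accuracy(matrix(c(0, 2, 3, 0), 2)), 0)
  # the headline count: 30 correct of 33 rounds to 91 percent
  cm33 <- diag(c(6, 8, 6, 4, 4, 2))
  dimnames(cm33) <- list(mas_levels(), mas_levels())
  cm33["0", "3"] <- 1; cm33["1", "0"] <- 1; cm33["1+", "2"] <- 1
  expect_equal(sum(cm33), 33)
  expect_equal(round(100 * accuracy(cm33)), 91)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("balanced accuracy is mean per-class recall", {
  # two classes with recalls 1.0 and 0.5
  expect_equal(balanced_accuracy(c("a", "a", "b", "b"),
                                 c("a", "a", "b", "a")), 0.75)
  set.seed(11)
  for (i in 1:10) {
    yt <- sample(c("0", "1", "2"), 60, replace = TRUE)
    yp <- sample(c("0", "1", "2"), 60, replace = TRUE)
    oracle <- mean(vapply(unique(yt), function(cl) {
      mean(yp[yt == cl] == cl)
    }, numeric(1)))
    expect_equal(balanced_accuracy(yt, yp), oracle)
    # equal class sizes: balanced accuracy equals plain accuracy
    yb <- rep(c("0", "1", "2"), each = 20)
    pb <- sample(c("0", "1", "2"), 60, replace = TRUE)
    expect_equal(balanced_accuracy(yb, pb),
                 accuracy(confusion_matrix(yb, pb, c("0", "1", "2"))))
  }
  # sample weights reweight the recalls
  expect_equal(balanced_accuracy(c("a", "a", "b"), c("a", "x", "b"),
                                 sample_weights = c(3, 1, 1)),
               mean(c(3 / 4, 1)))
})

test_that("weighted averages use unrounded values and supports", {
  pc <- data.frame(label = c("a", "b"), precision = c(0.8, 0.4),
                   recall = c(0.6, 1), f = c(0.686, 0.571),
                   support = c(3, 1))
  w <- weighted_average(pc)
  expect_equal(unname(w["precision"]), (3 * 0.8 + 0.4) / 4)
  # one class: its own metrics; equal supports: macro mean
  expect_equal(unname(weighted_average(pc[1, ])["f"]), 0.686)
  expect_equal(unname(weighted_average(pc, supports = c(1, 1))["recall"]),
               0.8)
  expect_error(weighted_average(pc, supports = 1:3), "supports")
  # identity: support-weighted recall equals accuracy
  set.seed(12)
  for (i in 1:10) {
    yt <- sample(mas_levels(), 80, replace = TRUE)
    yp <- sample(mas_levels(), 80, replace = TRUE)
    cm <- confusion_matrix(yt, yp)
    pr <- precision_recall_f(cm)
    keep <- pr$support > 0
    expect_equal(unname(weighted_average(pr[keep, ])["recall"]),
                 accuracy(cm))
  }
})

test_that("integer counts are reconstructed uniquely from rounded metrics", {
  r <- reconstruct_counts(0.50, 0.43, support = 7, max_predicted = 27)
  expect_identical(c(r$tp, r$predicted), c(3L, 6L))
  r <- reconstruct_counts(1.00, 1.00, support = 2, max_predicted = 27)
  expect_identical(c(r$tp, r$predicted), c(2L, 2L))
  r <- reconstruct_counts(0.25, 1.00, support = 2, max_predicted = 27)
  expect_identical(c(r$tp, r$predicted), c(2L, 8L))
  expect_error(reconstruct_counts(0.99, 0.01, support = 2, max_predicted = 27),
               "no integer counts")
  expect_error(reconstruct_counts(0.05, 1.00, support = 1, max_predicted = 30),
               "ambiguous")
})

test_that("evaluation report assembles consistent summaries and JSON", {
  set.seed(13)
  yt <- sample(mas_levels(), 50, replace = TRUE)
  yp <- yt
  yp[1:5] <- sample(mas_levels(), 5, replace = TRUE)
  rep <- evaluation_report(yt, yp)
  expect_equal(rep$accuracy, mean(yt == yp))
  expect_equal(sum(rep$per_class$support), 50L)
  expect_equal(unname(rep$weighted["recall"]), rep$accuracy)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$accuracy, rep$accuracy)
  expect_identical(js$labels, mas_levels())
  expect_output(print(rep), "MAS classification report")
})

test_that("bundled reference metrics have the expected shape", {
  ref <- reference_metrics()
  expect_setequal(unique(ref$classifier),
                  c("gaussian_nb", "decision_tree", "random_forest",
                    "xgboost", "svm", "logical_svm_rf"))
  base <- ref[ref$classifier == "svm", ]
  expect_identical(base$support, c(7L, 9L, 7L, 2L, 2L))
  expect_true(all(ref$precision >= 0 & ref$precision <= 1))
  expect_true(all(ref$recall >= 0 & ref$recall <= 1))
})
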