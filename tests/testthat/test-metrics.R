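test_that("confusion counts match a hand-enumerated vector pair", {
  # binary pair of length 10 constructed to give TP=3, FP=1, FN=2, TN=4
  # for the positive class (class 1)
  yt <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  yp <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  cc <- confusionCounts(yt, yp, 2)
  expect_equal(cc$tp[2], 3)
  expect_equal(cc$fp[2], 1)
  expect_equal(cc$fn[2], 2)
  expect_equal(cc$tn[2], 4)
  # one-vs-rest counts always total the sample count
  expect_equal(unname(cc$tp + cc$fp + cc$fn + cc$tn), c(10, 10))
  expect_error(confusionCounts(c(0, 2), c(0, 1), 2), "0..nClasses-1")
})

test_that("perfect and degenerate predictions give the expected counts", {
  cc <- confusionCounts(c(0, 1, 1, 0), c(0, 1, 1, 0), 2)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  expect_equal(macroF1(cc), 1)
  # all-one-class predictions: the other class's FN equals its support
  cc2 <- confusionCounts(c(0, 0, 0, 1, 1), rep(0, 5), 2)
  expect_equal(cc2$fn[2], 2)
})

test_that("F1 follows the precision/recall formula", {
  # precision 0.75, recall 0.6 -> F1 = 2 * 0.45 / 1.35 = 2/3
  # (TP = 3, FP = 1, FN = 2 realised by the enumerated pair above)
  yt <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  yp <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  cc <- confusionCounts(yt, yp, 2)
  expect_equal(classF1(cc, 1), 2 / 3, tolerance = 1e-12)
})

test_that("macro F1 equals the mean of independently computed per-class F1", {
  set.seed(41)
  for (rep in 1:5) {
    yt <- sample(0:2, 30, replace = TRUE)
    yp <- sample(0:2, 30, replace = TRUE)
    cc <- confusionCounts(yt, yp, 3)
    expect_equal(macroF1(cc), oracleMacroF1(yt, yp, 3), tolerance = 1e-12)
  }
})

test_that("macro F1 and balanced accuracy match counting oracles on 1000 random vectors", {
  set.seed(42)
  for (rep in 1:1000) {
    C <- sample(c(2L, 3L), 1)
    n <- sample(10:40, 1)
    yt <- sample(0:(C - 1), n, replace = TRUE)
    if (length(unique(yt)) < C) yt[seq_len(C)] <- 0:(C - 1)
    yp <- sample(0:(C - 1), n, replace = TRUE)
    cc <- confusionCounts(yt, yp, C)
    expect_equal(macroF1(cc), oracleMacroF1(yt, yp, C), tolerance = 1e-12)
    expect_equal(balancedAccuracy(cc), oracleMacroRecall(yt, yp, C),
                 tolerance = 1e-12)
  }
})

test_that("balanced accuracy averages per-class recalls and needs support", {
  # recalls 1.0 and 0.5 -> 0.75
  cc <- confusionCounts(c(0, 0, 1, 1), c(0, 0, 1, 0), 2)
  expect_equal(balancedAccuracy(cc), 0.75)
  expect_error(balancedAccuracy(confusionCounts(c(0, 0), c(0, 1), 2)),
               "undefined")
})

test_that("MCC matches the binary closed form and handles degeneracy", {
  yt <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  yp <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  cc <- confusionCounts(yt, yp, 2)
  tp <- 3; tn <- 4; fp <- 1; fn <- 2
  ref <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mccScore(cc), ref, tolerance = 1e-12)
  expect_equal(mccScore(confusionCounts(c(0, 1), c(0, 1), 2)), 1)
  expect_equal(mccScore(confusionCounts(c(0, 1), c(0, 0), 2)), 0)
})

test_that("AUC uses midranks: perfect 1, label-independent 0.5", {
  yt <- c(0, 0, 1, 1)
  perfect <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(evalMetrics(yt, perfect)$auc, 1)
  constant <- matrix(0.5, 4, 2)
  expect_equal(evalMetrics(yt, constant)$auc, 0.5)
  expect_error(evalMetrics(c(1, 1), matrix(0.5, 2, 2)), "single class")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (rep in 1:5) {
    y <- c(0, 1, sample(0:1, 28, replace = TRUE))
    s <- round(runif(30), 2)   # rounding forces ties
    P <- cbind(1 - s, s)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(evalMetrics(y, P)$auc, ref, tolerance = 1e-10)
  }
})

test_that("full metric report is coherent on a random prediction", {
  set.seed(44)
  y <- sample(0:3, 60, replace = TRUE)
  y[1:4] <- 0:3
  P <- randomProbMatrix(60, 4, 45)
  m <- evalMetrics(y, P)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$balanced_accuracy, m$recall, tolerance = 1e-12)
  expect_true(all(unlist(m[c("macro_f1", "precision", "recall",
                             "specificity", "auc")]) >= 0))
  expect_gte(m$mcc, -1)
  expect_lte(m$mcc, 1)
})

test_that("stratified folds balance sizes and class proportions", {
  labels <- rep(0:1, each = 50)
  f <- stratifiedKFold(labels, k = 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(20L, 5))
  for (k in 1:5)
    expect_equal(as.integer(table(labels[f == k])), c(10L, 10L))

  # 7 samples in 5 folds: sizes {2, 2, 1, 1, 1}
  f7 <- stratifiedKFold(rep(0, 7), k = 5, seed = 1)
  expect_equal(sort(as.integer(table(factor(f7, levels = 1:5))),
                    decreasing = TRUE), c(2L, 2L, 1L, 1L, 1L))

  # permuting labels with the same seed preserves the partition structure
  labs <- c(rep(0, 30), rep(1, 20))
  set.seed(9)
  perm <- sample(50)
  f1 <- stratifiedKFold(labs, k = 5, seed = 7)
  f2 <- stratifiedKFold(labs[perm], k = 5, seed = 7)
  expect_equal(sort(as.integer(table(f1))), sort(as.integer(table(f2))))
  for (k in 1:5)
    expect_equal(sort(as.integer(table(labs[f1 == k]))),
                 sort(as.integer(table(labs[perm][f2 == k]))))

  expect_error(stratifiedKFold(labels, k = 1), "k")
  expect_identical(stratifiedKFold(labels, 5, seed = 2),
                   stratifiedKFold(labels, 5, seed = 2))
})

test_that("t intervals reproduce printed mean +/- sd cases", {
  # construct 5 values with exact mean and sample sd, then summarise
  mkValues <- function(m, s) {
    base <- (1:5 - 3) / sd(1:5)
    m + s * base
  }
  ci <- tConfidenceInterval(mkValues(95.77, 0.61))
  expect_equal(round(unname(ci), 2), c(95.01, 96.53))
  ci2 <- tConfidenceInterval(mkValues(91.24, 1.03))
  expect_equal(round(unname(ci2), 2), c(89.96, 92.52))
  # all values equal -> zero-width interval at the mean
  expect_equal(unname(tConfidenceInterval(rep(4.2, 5))), c(4.2, 4.2))
  expect_error(tConfidenceInterval(1), "two values")
})
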