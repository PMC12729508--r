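#' One-vs-rest confusion counts
#'
#' Per-class true/false positive and negative counts from 0-based label
#' vectors. For each class `i`, predictions are treated one-vs-rest, so
#' `TP_i + FP_i + FN_i + TN_i` equals the total sample count.
#'
#' @param yTrue,yPred integer vectors of 0-based labels, equal length.
#' @param nClasses number of classes `C`; labels must lie in `0..C-1`.
#' @return A `confusionCounts` list with numeric vectors `tp`, `fp`, `fn`,
#'   `tn` (length `C`) and `nClasses`.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses) {
  nClasses <- checkCount(nClasses, "nClasses", 2L)
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length", call. = FALSE)
  if (anyNA(yTrue) || anyNA(yPred) ||
      any(c(yTrue, yPred) < 0L) || any(c(yTrue, yPred) >= nClasses))
    stop("labels must lie in 0..nClasses-1", call. = FALSE)
  n <- length(yTrue)
  tab <- matrix(0, nClasses, nClasses)   # rows: true, cols: predicted
  for (i in seq_len(n))
    tab[yTrue[i] + 1L, yPred[i] + 1L] <- tab[yTrue[i] + 1L, yPred[i] + 1L] + 1
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  tn <- n - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, table = tab,
                 nClasses = nClasses), class = "confusionCounts")
}

## 0/0 -> 0 convention keeps macro averages finite when a class is never
## predicted (or never occurs).
safeRatio <- function(num, den) ifelse(den > 0, num / den, 0)

#' Per-class and macro F1
#'
#' `F1 = 2 * precision * recall / (precision + recall)` with
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`; undefined
#' ratios (0/0) are taken as 0. The macro score is the unweighted mean of
#' the per-class F1 values over all `C` classes.
#'
#' @param counts a [confusionCounts()] object.
#' @param class 0-based class index.
#' @return Numeric scalar.
#' @examples
#' cc <- confusionCounts(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
#' macroF1(cc)
#' @export
classF1 <- function(counts, class) {
  stopifnot(inherits(counts, "confusionCounts"))
  i <- checkCount(class, "class", 0L) + 1L
  p <- safeRatio(counts$tp[i], counts$tp[i] + counts$fp[i])
  r <- safeRatio(counts$tp[i], counts$tp[i] + counts$fn[i])
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' @rdname classF1
#' @export
macroF1 <- function(counts) {
  stopifnot(inherits(counts, "confusionCounts"))
  mean(vapply(seq_len(counts$nClasses) - 1L,
              function(i) classF1(counts, i), 0))
}

#' Balanced accuracy
#'
#' The unweighted mean of per-class recalls
#' `TP_i / (TP_i + FN_i)`. Errors when a class is absent from the ground
#' truth (its recall is undefined).
#'
#' @param counts a [confusionCounts()] object.
#' @return Numeric scalar in `[0, 1]`.
#' @export
balancedAccuracy <- function(counts) {
  stopifnot(inherits(counts, "confusionCounts"))
  support <- counts$tp + counts$fn
  if (any(support == 0))
    stop("balanced accuracy undefined: some class has no true samples",
         call. = FALSE)
  mean(counts$tp / support)
}

## Midrank (Wilcoxon) AUC for one binary split; ties share midranks, so
## label-independent scores give exactly 0.5.
aucBinary <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: ground truth contains a single class",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass correlation coefficient (MCC)
#'
#' Matthews correlation generalised to `C` classes from the confusion
#' matrix: `(c*s - sum(t*p)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))`
#' with `c` the correctly classified count, `s` the sample count, `t` the
#' true-class totals and `p` the predicted-class totals. Degenerate
#' denominators give 0. For binary problems this equals the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' @param counts a [confusionCounts()] object.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
mccScore <- function(counts) {
  stopifnot(inherits(counts, "confusionCounts"))
  tab <- counts$table
  s <- sum(tab)
  c0 <- sum(diag(tab))
  t <- rowSums(tab)
  p <- colSums(tab)
  num <- c0 * s - sum(t * p)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) 0 else num / den
}

#' Full metric report for a prediction
#'
#' Computes macro F1, balanced accuracy, macro precision, macro recall
#' (identical to sensitivity), macro specificity (`TN / (TN + FP)`), MCC
#' and AUC (midrank; unweighted one-vs-rest mean for more than two classes)
#' from true labels and a class-probability matrix. Predicted labels are
#' the row-wise argmax.
#'
#' @param yTrue 0-based true labels.
#' @param scores [ProbabilityMatrix-class] or plain probability matrix.
#' @param binaryF1 when `TRUE` and the task is binary, report the
#'   positive-class (class 1) F1 instead of macro F1.
#' @return Named list of metric values in `[0, 1]` (MCC in `[-1, 1]`).
#' @export
evalMetrics <- function(yTrue, scores, binaryF1 = FALSE) {
  P <- if (is(scores, "ProbabilityMatrix")) probs(scores) else scores
  stopifnot(is.matrix(P), nrow(P) == length(yTrue))
  nClasses <- ncol(P)
  yTrue <- as.integer(yTrue)
  yPred <- max.col(P, ties.method = "first") - 1L
  cc <- confusionCounts(yTrue, yPred, nClasses)
  prec <- mean(safeRatio(cc$tp, cc$tp + cc$fp))
  rec <- mean(safeRatio(cc$tp, cc$tp + cc$fn))
  spec <- mean(safeRatio(cc$tn, cc$tn + cc$fp))
  auc <- if (nClasses == 2L) {
    aucBinary(P[, 2L], yTrue == 1L)
  } else {
    mean(vapply(seq_len(nClasses) - 1L,
                function(c) aucBinary(P[, c + 1L], yTrue == c), 0))
  }
  f1 <- if (binaryF1 && nClasses == 2L) classF1(cc, 1L) else macroF1(cc)
  list(macro_f1 = f1,
       balanced_accuracy = balancedAccuracy(cc),
       precision = prec, recall = rec, sensitivity = rec,
       specificity = spec, auc = auc, mcc = mccScore(cc))
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds. With `stratified = TRUE`
#' (default) samples are shuffled within each class and dealt round-robin,
#' continuing the cycle across classes, so per-class proportions are
#' preserved up to rounding and overall fold sizes differ by at most one.
#'
#' @param labels 0-based class labels (any integer coding works).
#' @param k number of folds (>= 2).
#' @param seed shuffling seed.
#' @param stratified preserve class proportions per fold.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @examples
#' table(stratifiedKFold(rep(0:1, each = 50), k = 5, seed = 1))
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  k <- checkCount(k, "k", 2L)
  n <- length(labels)
  if (n < k) stop("need at least k samples", call. = FALSE)
  folds <- integer(n)
  withSeed(seed, {
    if (stratified) {
      offset <- 0L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- offset + length(idx)
      }
    } else {
      idx <- sample.int(n)
      folds[idx] <- ((seq_len(n) - 1L) %% k) + 1L
    }
  })
  folds
}

#' Student-t confidence interval
#'
#' Two-sided `level` confidence interval for the mean of `n` values:
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` with the sample standard
#' deviation (divisor `n - 1`).
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @examples
#' round(tConfidenceInterval(c(95.77 + 0.61 * scale(c(1:5))[, 1])), 2)
#' @export
tConfidenceInterval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L)
    stop("need at least two values for a t interval", call. = FALSE)
  level <- checkNumber(level, "level", 0, 1)
  m <- mean(values)
  half <- qt((1 + level) / 2, df = n - 1L) * sd(values) / sqrt(n)
  c(low = m - half, high = m + half)
}

## Interval straight from a printed mean and sample sd (no raw values).
tIntervalFromMeanSd <- function(mean, sd, n, level = 0.95) {
  half <- qt((1 + level) / 2, df = n - 1L) * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

#' Summarise per-fold metric values
#'
#' Builds a [CVSummary-class] with mean, sample standard deviation and the
#' Student-t confidence interval of the per-fold values.
#'
#' @param values per-fold metric values (length >= 2).
#' @param metric,model names recorded in the summary.
#' @param level confidence level.
#' @return A [CVSummary-class].
#' @export
cvSummary <- function(values, metric = "metric", model = "model",
                      level = 0.95) {
  ci <- tConfidenceInterval(values, level)
  new("CVSummary", metric = metric, model = model,
      perFold = as.numeric(values), mean = mean(values), sd = sd(values),
      ciLow = unname(ci[1]), ciHigh = unname(ci[2]), level = level)
}
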