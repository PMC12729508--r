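#' Fusion configuration
#'
#' How to combine two models' class-probability matrices: a convex weighted
#' average with a grid-searched weight (default; grid step 0.1 over
#' `[0, 1]`), a simple average (the weighted average at `w = 0.5`), or a
#' stacked meta-learner (multinomial logistic regression or a 2-layer
#' neural network) trained on the concatenated probabilities.
#'
#' @param method one of `"weighted_average"`, `"simple_average"`,
#'   `"logistic"`, `"two_layer_nn"`.
#' @param gridStep grid spacing for the weight search; must divide 1 into a
#'   whole number of steps.
#' @param selectionMetric metric maximised by the grid search
#'   (`"macro_f1"` or `"balanced_accuracy"`).
#' @param seed seed for meta-learner training.
#' @param nnHidden hidden width of the 2-layer meta network.
#' @return A validated `fusionConfig` list.
#' @export
fusionConfig <- function(method = c("weighted_average", "simple_average",
                                    "logistic", "two_layer_nn"),
                         gridStep = 0.1, selectionMetric = "macro_f1",
                         seed = 1L, nnHidden = 16L) {
  method <- match.arg(method)
  gridStep <- checkNumber(gridStep, "gridStep", 1e-6, 1)
  if (abs(1 / gridStep - round(1 / gridStep)) > 1e-9)
    stop("gridStep must divide 1 evenly", call. = FALSE)
  if (!selectionMetric %in% c("macro_f1", "balanced_accuracy"))
    stop("selectionMetric must be 'macro_f1' or 'balanced_accuracy'",
         call. = FALSE)
  structure(list(method = method, gridStep = gridStep,
                 selectionMetric = selectionMetric,
                 seed = checkCount(seed, "seed", min = -.Machine$integer.max),
                 nnHidden = checkCount(nnHidden, "nnHidden")),
            class = "fusionConfig")
}

asProbs <- function(p) if (is(p, "ProbabilityMatrix")) probs(p) else p

checkAligned <- function(pA, pB) {
  A <- asProbs(pA)
  B <- asProbs(pB)
  if (!all(dim(A) == dim(B)))
    stop("probability matrices must have identical shape", call. = FALSE)
  if (is(pA, "ProbabilityMatrix") && is(pB, "ProbabilityMatrix") &&
      !identical(sampleIds(pA), sampleIds(pB)))
    stop("probability matrices must be in the same sample order",
         call. = FALSE)
  list(A = A, B = B)
}

#' Weighted average of two probability matrices
#'
#' Row-wise convex combination `w * P_A + (1 - w) * P_B`. Endpoints return
#' the inputs exactly, and rows stay valid probability vectors for any
#' `w` in `[0, 1]`.
#'
#' @param pA,pB [ProbabilityMatrix-class] objects (or plain matrices) with
#'   identical shape and sample order.
#' @param w weight of model A in `[0, 1]`.
#' @return A [ProbabilityMatrix-class].
#' @examples
#' a <- ProbabilityMatrix(matrix(c(0.8, 0.2), 1))
#' b <- ProbabilityMatrix(matrix(c(0.4, 0.6), 1))
#' probs(weightedAverage(a, b, 0.5))   # (0.6, 0.4)
#' @export
weightedAverage <- function(pA, pB, w) {
  w <- checkNumber(w, "w", 0, 1)
  m <- checkAligned(pA, pB)
  ids <- if (is(pA, "ProbabilityMatrix")) sampleIds(pA)
         else paste0("s", seq_len(nrow(m$A)))
  ProbabilityMatrix(w * m$A + (1 - w) * m$B, sampleIds = ids)
}

#' Grid search for the fusion weight
#'
#' Evaluates the selection metric of the weighted average at every grid
#' point `0, step, ..., 1` on a labeled selection split and returns the
#' maximising weight (ties go to the smallest `w`). Because the grid
#' contains both endpoints, the selected fusion is never worse than either
#' single model on the selection split.
#'
#' @param pA,pB probability matrices on the selection split.
#' @param yTrue 0-based labels of the selection split.
#' @param cfg a [fusionConfig()].
#' @return The chosen weight (scalar in the grid).
#' @export
gridSearchWeight <- function(pA, pB, yTrue, cfg = fusionConfig()) {
  m <- checkAligned(pA, pB)
  if (length(yTrue) == 0L || nrow(m$A) != length(yTrue))
    stop("selection split labels must match the probability rows",
         call. = FALSE)
  nSteps <- round(1 / cfg$gridStep)
  grid <- (0:nSteps) / nSteps
  vals <- vapply(grid, function(w) {
    fused <- w * m$A + (1 - w) * m$B
    evalMetrics(yTrue, fused)[[cfg$selectionMetric]]
  }, 0)
  grid[which.max(vals)]
}

#' Stacked meta-learner over two models' probabilities
#'
#' Trains a meta-model on the `2 * C` concatenated class probabilities of
#' the two base models: multinomial logistic regression
#' (`method = "logistic"`) or a 2-layer neural network with ReLU hidden
#' layer (`method = "two_layer_nn"`), both optimised with Adam and
#' cross-entropy. Deterministic under the seed.
#'
#' @param pATrain,pBTrain probability matrices on the meta-training split.
#' @param yTrain 0-based labels of that split.
#' @param method `"logistic"` or `"two_layer_nn"`.
#' @param cfg a [fusionConfig()] (provides seed and hidden width).
#' @param tc a [trainConfig()] for the meta-optimiser.
#' @return A `metaModel`; apply with [predictProba()] passing
#'   `newdata = list(pA, pB)`.
#' @export
stackMeta <- function(pATrain, pBTrain, yTrain,
                      method = c("logistic", "two_layer_nn"),
                      cfg = fusionConfig(), tc = trainConfig()) {
  method <- match.arg(method)
  m <- checkAligned(pATrain, pBTrain)
  yTrain <- as.integer(yTrain)
  nClasses <- ncol(m$A)
  if (length(unique(yTrain)) < 2L)
    stop("meta-training labels contain a single class", call. = FALSE)
  X <- cbind(m$A, m$B)
  hidden <- if (method == "two_layer_nn") cfg$nnHidden else integer(0)
  mlp <- mlpTrain(X, yTrain, nClasses, hidden = hidden,
                  lr = tc$learningRate, epochs = tc$epochs,
                  batchSize = tc$batchSize, seed = cfg$seed)
  structure(list(mlp = mlp, method = method, nClasses = nClasses),
            class = "metaModel")
}

#' @rdname predictProba
#' @export
predictProba.metaModel <- function(object, newdata, ...) {
  stopifnot(is.list(newdata), length(newdata) == 2L)
  m <- checkAligned(newdata[[1]], newdata[[2]])
  ids <- if (is(newdata[[1]], "ProbabilityMatrix")) sampleIds(newdata[[1]])
         else paste0("s", seq_len(nrow(m$A)))
  ProbabilityMatrix(mlpPredictProba(object$mlp, cbind(m$A, m$B)),
                    sampleIds = ids)
}

#' Fuse two models' predictions
#'
#' High-level fusion: selects the weight (or fits the meta-learner) on a
#' labeled selection split and applies the resulting rule to the test
#' split. The test labels are never used for selection.
#'
#' @param pASel,pBSel probability matrices on the selection split.
#' @param ySel selection-split labels.
#' @param pATest,pBTest probability matrices on the test split.
#' @param cfg a [fusionConfig()].
#' @param tc a [trainConfig()] for meta-learners.
#' @return List with `fused` ([ProbabilityMatrix-class] on the test split),
#'   `chosenWeight` (`NA` for meta methods) and `method`.
#' @export
fusePredictions <- function(pASel, pBSel, ySel, pATest, pBTest,
                            cfg = fusionConfig(), tc = trainConfig()) {
  w <- NA_real_
  fused <- switch(cfg$method,
    weighted_average = {
      w <- gridSearchWeight(pASel, pBSel, ySel, cfg)
      weightedAverage(pATest, pBTest, w)
    },
    simple_average = {
      w <- 0.5
      weightedAverage(pATest, pBTest, 0.5)
    },
    logistic = ,
    two_layer_nn = {
      meta <- stackMeta(pASel, pBSel, ySel, method = cfg$method,
                        cfg = cfg, tc = tc)
      predictProba(meta, list(pATest, pBTest))
    })
  list(fused = fused, chosenWeight = w, method = cfg$method)
}
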