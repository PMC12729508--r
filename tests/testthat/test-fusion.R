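test_that("weighted average obeys endpoint, idempotence and arithmetic laws", {
  A <- ProbabilityMatrix(randomProbMatrix(6, 3, 1))
  B <- ProbabilityMatrix(randomProbMatrix(6, 3, 2))
  expect_equal(probs(weightedAverage(A, B, 1)), probs(A))
  expect_equal(probs(weightedAverage(A, B, 0)), probs(B))
  for (w in c(0, 0.3, 0.8, 1))
    expect_equal(probs(weightedAverage(A, A, w)), probs(A))
  a <- ProbabilityMatrix(matrix(c(0.8, 0.2), 1))
  b <- ProbabilityMatrix(matrix(c(0.4, 0.6), 1))
  expect_equal(drop(probs(weightedAverage(a, b, 0.5))), c(0.6, 0.4))
  expect_error(weightedAverage(A, ProbabilityMatrix(randomProbMatrix(5, 3, 3)),
                               0.5), "identical shape")
})

test_that("fused rows are convex combinations and remain probabilities", {
  A <- randomProbMatrix(10, 4, 4)
  B <- randomProbMatrix(10, 4, 5)
  for (w in seq(0, 1, 0.25)) {
    Fm <- probs(weightedAverage(A, B, w))
    expect_equal(rowSums(Fm), rep(1, 10), tolerance = 1e-12)
    expect_true(all(Fm >= pmin(A, B) - 1e-12))
    expect_true(all(Fm <= pmax(A, B) + 1e-12))
  }
})

test_that("grid search equals an independent 11-point enumeration", {
  set.seed(6)
  for (rep in 1:5) {
    y <- sample(0:1, 30, replace = TRUE)
    y[1:2] <- 0:1
    A <- randomProbMatrix(30, 2, 60 + rep)
    B <- randomProbMatrix(30, 2, 70 + rep)
    cfg <- fusionConfig()
    got <- gridSearchWeight(A, B, y, cfg)
    # independent enumeration over the same grid
    grid <- (0:10) / 10
    vals <- vapply(grid, function(w) {
      yp <- max.col(w * A + (1 - w) * B) - 1L
      oracleMacroF1(y, yp, 2)
    }, 0)
    expect_equal(got, grid[which.max(vals)])
    # selection metric at the chosen w dominates both endpoints
    expect_gte(vals[match(got, grid)], max(vals[1], vals[11]) - 1e-12)
  }
})

test_that("a perfect model is never out-voted by a random one", {
  y <- rep(0:1, each = 5)
  perfect <- cbind(1 - y, y) * 0.98 + 0.01
  random <- randomProbMatrix(10, 2, 8)
  w <- gridSearchWeight(perfect, random, y, fusionConfig())
  fusedPred <- max.col(probs(weightedAverage(perfect, random, w))) - 1L
  expect_equal(oracleMacroF1(y, fusedPred, 2), 1)   # chosen fusion perfect
  # a confidently wrong partner forces the grid onto the perfect endpoint
  wrong <- cbind(y, 1 - y) * 0.98 + 0.01
  w2 <- gridSearchWeight(perfect, wrong, y, fusionConfig())
  fused2 <- max.col(probs(weightedAverage(perfect, wrong, w2))) - 1L
  expect_equal(oracleMacroF1(y, fused2, 2), 1)
  expect_gte(w2, 0.6)   # ties resolve to the smallest winning weight
})

test_that("simple average equals the weighted average at w = 0.5", {
  A <- ProbabilityMatrix(randomProbMatrix(8, 2, 9))
  B <- ProbabilityMatrix(randomProbMatrix(8, 2, 10))
  res <- fusePredictions(A, B, rep(0:1, 4), A, B,
                         fusionConfig(method = "simple_average"))
  expect_equal(probs(res$fused), probs(weightedAverage(A, B, 0.5)))
  expect_equal(res$chosenWeight, 0.5)
})

test_that("meta-learners pass through a perfectly informative model", {
  set.seed(11)
  y <- rep(0:1, each = 20)
  A <- cbind(1 - y, y) * 0.9 + 0.05           # perfectly informative
  B <- randomProbMatrix(40, 2, 12)
  for (method in c("logistic", "two_layer_nn")) {
    meta <- stackMeta(A, B, y, method = method,
                      cfg = fusionConfig(method = method, seed = 3),
                      tc = smallTrainConfig(epochs = 150, lr = 5e-2,
                                            batchSize = 40))
    p <- probs(predictProba(meta, list(A, B)))
    expect_gte(mean((max.col(p) - 1L) == y), 0.95)
  }
})

test_that("constant meta-features collapse to the majority class", {
  y <- c(rep(0L, 15), rep(1L, 5))
  A <- matrix(0.5, 20, 2)
  B <- matrix(0.5, 20, 2)
  meta <- stackMeta(A, B, y, method = "logistic",
                    cfg = fusionConfig(seed = 4),
                    tc = smallTrainConfig(epochs = 200, lr = 5e-2,
                                          batchSize = 20))
  p <- probs(predictProba(meta, list(A, B)))
  expect_true(all(max.col(p) == 1))   # predicts class 0, the majority
})

test_that("logistic meta-learner separates a linearly separable stack", {
  set.seed(13)
  y <- rep(0:1, each = 15)
  A <- cbind(1 - y, y) * 0.8 + 0.1
  B <- matrix(0.5, 30, 2)
  meta <- stackMeta(A, B, y, method = "logistic",
                    cfg = fusionConfig(seed = 5),
                    tc = trainConfig(learningRate = 0.1, epochs = 300,
                                     batchSize = 30, seed = 5))
  p <- probs(predictProba(meta, list(A, B)))
  expect_equal(mean((max.col(p) - 1L) == y), 1)   # 100% training accuracy
  expect_error(stackMeta(A, B, rep(0, 30), method = "logistic"),
               "single class")
})

test_that("meta-learner training is deterministic under its seed", {
  y <- rep(0:1, each = 10)
  A <- randomProbMatrix(20, 2, 21)
  B <- randomProbMatrix(20, 2, 22)
  m1 <- stackMeta(A, B, y, "two_layer_nn", fusionConfig(seed = 6),
                  smallTrainConfig(epochs = 20))
  m2 <- stackMeta(A, B, y, "two_layer_nn", fusionConfig(seed = 6),
                  smallTrainConfig(epochs = 20))
  expect_identical(probs(predictProba(m1, list(A, B))),
                   probs(predictProba(m2, list(A, B))))
})

test_that("fusion config validates its grid", {
  expect_error(fusionConfig(gridStep = 0.3), "divide 1")
  expect_error(fusionConfig(selectionMetric = "accuracy"), "selectionMetric")
  expect_silent(fusionConfig(gridStep = 0.05))
})
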