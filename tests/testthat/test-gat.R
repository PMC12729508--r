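test_that("compiled forward pass matches an independent R implementation", {
  cfg <- gatConfig(inDim = 6, nClasses = 3, initSeed = 2)
  params <- initGATParams(cfg)
  for (seed in 1:4) {
    g <- makeRandomGraph(sample(2:9, 1), 6, threshold = -0.2, seed = seed)
    got <- drop(gatForward(list(params = params, config = cfg), list(g)))
    ref <- refGatLogits(params, g, cfg)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with central differences", {
  cfg <- gatConfig(inDim = 5, nClasses = 2, initSeed = 7)
  params <- initGATParams(cfg)
  graphs <- list(makeRandomGraph(4, 5, 0L, threshold = 0, seed = 1),
                 makeRandomGraph(6, 5, 1L, threshold = 0, seed = 2),
                 makeRandomGraph(1, 5, 0L, threshold = 0, seed = 3))
  b <- HistoGraphFusion:::graphsToBatch(graphs, 5)
  y <- c(0L, 1L, 0L)
  lossAt <- function(p)
    HistoGraphFusion:::gat_loss_grad_cpp(p, b$X, b$nodePtr, b$edges,
                                         b$edgePtr, y, 4L, 8L, 4L, 4L,
                                         0.2, TRUE)$loss
  lg <- HistoGraphFusion:::gat_loss_grad_cpp(params, b$X, b$nodePtr,
                                             b$edges, b$edgePtr, y,
                                             4L, 8L, 4L, 4L, 0.2, TRUE)
  set.seed(10)
  for (pn in names(params)) {
    for (i in sample(seq_along(params[[pn]]), min(6, length(params[[pn]])))) {
      h <- 1e-5
      up <- params; up[[pn]][i] <- up[[pn]][i] + h
      dn <- params; dn[[pn]][i] <- dn[[pn]][i] - h
      num <- (lossAt(up) - lossAt(dn)) / (2 * h)
      expect_equal(lg$grads[[pn]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("node representations have widths 32 then 16 by default", {
  cfg <- gatConfig(inDim = 12, nClasses = 4)
  out <- gatForward(list(params = initGATParams(cfg), config = cfg),
                    list(makeRandomGraph(10, 12, seed = 5)),
                    returnIntermediates = TRUE)
  expect_equal(ncol(out$h1), 32)
  expect_equal(ncol(out$h2), 16)
  expect_equal(ncol(out$logits), 4)
  expect_equal(cfg$layer1Heads * cfg$layer1PerHead, 32)
  expect_equal(cfg$layer2Heads * cfg$layer2PerHead, 16)
})

test_that("logits are invariant to node permutations", {
  cfg <- gatConfig(inDim = 7, nClasses = 2, initSeed = 4)
  params <- initGATParams(cfg)
  for (seed in 1:3) {
    g <- makeRandomGraph(8, 7, threshold = 0, seed = 40 + seed)
    set.seed(seed)
    perm <- sample(8)
    inv <- order(perm)
    e <- graphEdges(g)
    g2 <- ImageGraph(nodeFeatures(g)[perm, ],
                     cbind(inv[e[, 1]], inv[e[, 2]]), "perm")
    l1 <- gatForward(list(params = params, config = cfg), list(g))
    l2 <- gatForward(list(params = params, config = cfg), list(g2))
    expect_equal(l1, l2, tolerance = 1e-10)
  }
})

test_that("single-node pooling equals that node's layer-2 output", {
  cfg <- gatConfig(inDim = 5, nClasses = 2, initSeed = 3)
  out <- gatForward(list(params = initGATParams(cfg), config = cfg),
                    list(makeRandomGraph(1, 5, seed = 9)),
                    returnIntermediates = TRUE)
  expect_equal(drop(out$pooled), drop(out$h2), tolerance = 1e-12)
})

test_that("edgeless graphs still produce finite logits via self-loops", {
  cfg <- gatConfig(inDim = 4, nClasses = 2, initSeed = 6)
  g <- ImageGraph(matrix(rnorm(12), 3, 4))   # no edges at all
  logits <- gatForward(list(params = initGATParams(cfg), config = cfg),
                       list(g))
  expect_true(all(is.finite(logits)))
})

test_that("batched and one-by-one inference agree", {
  cfg <- gatConfig(inDim = 6, nClasses = 2, initSeed = 8)
  params <- initGATParams(cfg)
  graphs <- lapply(1:5, function(s)
    makeRandomGraph(sample(1:7, 1), 6, threshold = 0, seed = 50 + s))
  batched <- gatForward(list(params = params, config = cfg), graphs)
  single <- t(vapply(graphs, function(g)
    drop(gatForward(list(params = params, config = cfg), list(g))),
    numeric(2)))
  expect_equal(batched, single, tolerance = 1e-5)
})

test_that("training is deterministic, learns separable data, errors on bad input", {
  spec <- syntheticSpec(nImages = 30, nClasses = 2, patchGrid = c(4, 4),
                        featureDim = 12, classSeparation = 5, seed = 17)
  ds <- generateFeatureDataset(spec)
  graphs <- buildGraphs(ds$features, graphBuildConfig(nClusters = 6),
                        ds$labels)
  cfg <- gatConfig(inDim = 12, nClasses = 2, initSeed = 1)
  tc <- smallTrainConfig(epochs = 40, lr = 2e-3, seed = 5)
  m1 <- trainGAT(graphs[1:24], cfg, tc)
  m2 <- trainGAT(graphs[1:24], cfg, tc)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$lossHistory[40], m1$lossHistory[1])
  met <- evalMetrics(ds$labels[25:30], predictProba(m1, graphs[25:30]))
  expect_gte(met$macro_f1, 0.9)

  unlabeled <- graphs
  unlabeled[[1]] <- ImageGraph(nodeFeatures(graphs[[1]]),
                               graphEdges(graphs[[1]]), "u")
  expect_error(trainGAT(unlabeled, cfg, tc), "labeled")
  expect_error(trainGAT(graphs[c(1, 3)], cfg, tc), "class")  # one class only
  expect_error(trainGAT(graphs, gatConfig(inDim = 99, nClasses = 2), tc),
               "width")
})

test_that("shuffled labels give chance-level held-out balanced accuracy", {
  spec <- syntheticSpec(nImages = 40, nClasses = 2, patchGrid = c(4, 4),
                        featureDim = 10, classSeparation = 5, seed = 23)
  ds <- generateFeatureDataset(spec)
  graphs <- buildGraphs(ds$features, graphBuildConfig(nClusters = 6))
  accs <- vapply(1:3, function(seed) {
    set.seed(100 + seed)
    yShuf <- sample(ds$labels)
    tr <- 1:30
    te <- 31:40
    m <- trainGAT(graphs[tr], gatConfig(10, 2, initSeed = seed),
                  smallTrainConfig(epochs = 40, lr = 2e-3, seed = seed),
                  labels = yShuf[tr])
    p <- probs(predictProba(m, graphs[te]))
    yPred <- max.col(p) - 1L
    cc <- confusionCounts(yShuf[te], yPred, 2)
    balancedAccuracy(cc)
  }, 0)
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("softmax predictions are valid and match closed forms", {
  expect_equal(drop(softmaxRows(c(0, 0))), c(0.5, 0.5))
  expect_equal(drop(softmaxRows(c(log(3), 0))), c(0.75, 0.25))
  set.seed(31)
  L <- matrix(rnorm(40), 10, 4)
  expect_equal(rowSums(softmaxRows(L)), rep(1, 10), tolerance = 1e-12)

  cfg <- gatConfig(inDim = 5, nClasses = 2, initSeed = 2)
  graphs <- list(makeRandomGraph(4, 5, 0L, seed = 1),
                 makeRandomGraph(5, 5, 1L, seed = 2))
  m <- trainGAT(graphs, cfg, smallTrainConfig(epochs = 3, seed = 1))
  pm <- predictProba(m, graphs)
  expect_s4_class(pm, "ProbabilityMatrix")
  expect_equal(rowSums(probs(pm)), c(1, 1), tolerance = 1e-9)
  expect_equal(sampleIds(pm), vapply(graphs, imageId, ""))
})

test_that("models round-trip through the JSON checkpoint", {
  graphs <- list(makeRandomGraph(4, 5, 0L, seed = 1),
                 makeRandomGraph(5, 5, 1L, seed = 2))
  m <- trainGAT(graphs, gatConfig(5, 2, initSeed = 3),
                smallTrainConfig(epochs = 5, seed = 2))
  path <- tempfile(fileext = ".json")
  saveGATModel(m, path)
  back <- loadGATModel(path)
  expect_equal(probs(predictProba(back, graphs)),
               probs(predictProba(m, graphs)), tolerance = 1e-12)
  unlink(path)
})
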