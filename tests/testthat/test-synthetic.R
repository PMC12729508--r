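test_that("spec validation rejects impossible datasets", {
  expect_error(syntheticSpec(nClasses = 3), "2 or 4")
  expect_error(syntheticSpec(nImages = 1, nClasses = 2), "every class")
  expect_error(syntheticSpec(featureDim = 0), "featureDim")
  expect_error(syntheticSpec(classSeparation = -1), "classSeparation")
})

test_that("feature datasets have the declared geometry and balanced labels", {
  spec <- syntheticSpec(nImages = 10, nClasses = 4, patchGrid = c(14, 14),
                        featureDim = 768, seed = 3)
  ds <- generateFeatureDataset(spec)
  expect_length(ds$features, 10)
  expect_equal(dim(features(ds$features[[1]])), c(196, 768))
  counts <- table(ds$labels)
  expect_equal(length(counts), 4L)           # every class appears
  expect_lte(max(counts) - min(counts), 1)   # balanced up to rounding
})

test_that("identical specs reproduce identical feature datasets", {
  spec <- syntheticSpec(nImages = 6, featureDim = 16, patchGrid = c(3, 3),
                        seed = 11)
  a <- generateFeatureDataset(spec)
  b <- generateFeatureDataset(spec)
  expect_identical(a$labels, b$labels)
  for (i in seq_along(a$features))
    expect_identical(features(a$features[[i]]), features(b$features[[i]]))
})

test_that("degenerate mixture collapses to exact class means", {
  spec <- syntheticSpec(nImages = 4, nClasses = 2, patchGrid = c(2, 2),
                        featureDim = 8, nComponents = 1, noiseSd = 0,
                        classSeparation = 2, seed = 5)
  ds <- generateFeatureDataset(spec)
  for (i in 1:4) {
    X <- features(ds$features[[i]])
    expect_equal(max(apply(X, 2, function(col) diff(range(col)))), 0)
  }
  # same class -> identical mean vector; other class -> shifted
  expect_identical(features(ds$features[[1]])[1, ],
                   features(ds$features[[3]])[1, ])
  expect_false(isTRUE(all.equal(features(ds$features[[1]])[1, ],
                                features(ds$features[[2]])[1, ])))
})

test_that("zero separation makes per-class distributions identical", {
  mk <- function(seed) generateFeatureDataset(
    syntheticSpec(nImages = 4, nClasses = 2, patchGrid = c(2, 2),
                  featureDim = 8, nComponents = 2, noiseSd = 0,
                  classSeparation = 0, seed = seed))
  ds <- mk(9)
  # with zero separation the component means are shared, so patch rows of
  # both classes come from the same finite set of vectors
  rowsOf <- function(i) apply(features(ds$features[[i]]), 1,
                              paste, collapse = ",")
  expect_true(all(rowsOf(2) %in%
                  c(rowsOf(1), rowsOf(3), rowsOf(2))))
  pool01 <- unique(c(rowsOf(1), rowsOf(2), rowsOf(3), rowsOf(4)))
  expect_lte(length(pool01), 2)   # only 2 distinct component means exist
})

test_that("image datasets are deterministic and balanced", {
  spec <- syntheticSpec(nImages = 4, nClasses = 4, imageSize = 32, seed = 2)
  a <- generateImageDataset(spec)
  b <- generateImageDataset(spec)
  expect_equal(as.integer(table(a$labels)), rep(1L, 4))
  for (i in 1:4)
    expect_identical(pixels(a$images[[i]]), pixels(b$images[[i]]))
  expect_true(all(vapply(a$images, function(im)
    all(pixels(im) >= 0 & pixels(im) <= 1), TRUE)))
  expect_error(generateImageDataset(
    syntheticSpec(nImages = 4, imageSize = 16)), "imageSize")
})

test_that("feature datasets round-trip through the CSV persistence layer", {
  spec <- syntheticSpec(nImages = 4, featureDim = 6, patchGrid = c(2, 2),
                        seed = 7)
  ds <- generateFeatureDataset(spec)
  dir <- tempfile("featds")
  writeFeatureDataset(ds, dir)
  back <- readFeatureDataset(dir)
  expect_equal(back$labels, ds$labels)
  for (i in seq_along(ds$features))
    expect_equal(features(back$features[[i]]), features(ds$features[[i]]),
                 tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("image datasets round-trip through the PNG folder layout", {
  spec <- syntheticSpec(nImages = 4, nClasses = 2, imageSize = 32,
                        noiseSd = 0.5, seed = 13)
  ds <- generateImageDataset(spec)
  dir <- tempfile("imgds")
  writeImageDataset(ds, dir)
  back <- readImageFolder(dir)
  expect_equal(back$labels, sort(ds$labels))
  expect_equal(back$classNames, c("class_0", "class_1"))
  # 8-bit PNG quantisation: pixels match within half a grey level
  orig <- pixels(ds$images[[1]])
  got <- pixels(back$images[[which(vapply(back$images, imageId, "") ==
                                   imageId(ds$images[[1]]))]])
  expect_lt(max(abs(orig - got)), 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("downstream class signal grows with class separation", {
  # cross-validated macro F1 non-decreasing over separations {0, 1, 5},
  # majority vote over 3 seeds at reduced problem size
  runF1 <- function(sep, seed) {
    spec <- syntheticSpec(nImages = 40, nClasses = 2, patchGrid = c(5, 5),
                          featureDim = 16, nComponents = 2,
                          classSeparation = sep, seed = seed)
    ds <- generateFeatureDataset(spec)
    graphs <- buildGraphs(ds$features, graphBuildConfig(nClusters = 8),
                          ds$labels)
    folds <- stratifiedKFold(ds$labels, k = 5, seed = seed)
    f1 <- numeric(5)
    for (f in 1:5) {
      tr <- which(folds != f)
      te <- which(folds == f)
      m <- trainGAT(graphs[tr], gatConfig(16, 2, initSeed = seed),
                    smallTrainConfig(epochs = 60, lr = 2e-3, seed = seed))
      f1[f] <- evalMetrics(ds$labels[te],
                           predictProba(m, graphs[te]))$macro_f1
    }
    mean(f1)
  }
  seps <- c(0, 1, 5)
  wins01 <- 0; wins15 <- 0
  for (seed in 1:3) {
    f1s <- vapply(seps, runF1, 0, seed = seed)
    if (f1s[2] >= f1s[1] - 0.05) wins01 <- wins01 + 1
    if (f1s[3] >= f1s[2] - 0.05) wins15 <- wins15 + 1
  }
  expect_gte(wins01, 2)
  expect_gte(wins15, 2)
})
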