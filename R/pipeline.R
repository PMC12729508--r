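#' End-to-end experiment configuration
#'
#' Bundles every stage of the cross-validated experiment: data source
#' (synthetic spec or a dataset directory), feature extraction, graph
#' construction, the graph classifier, the baseline, fusion and evaluation.
#' Each stage's seed is derived from `globalSeed` with a fixed offset
#' scheme, so a single integer reproduces the whole run.
#'
#' @param spec a [syntheticSpec()] describing the synthetic dataset (ignored
#'   when `dataDir` is given).
#' @param mode `"features"` (patch-feature matrices; baseline mean-pools
#'   them) or `"images"` (raw images; toy extractor + trainable conv
#'   baseline with augmentation).
#' @param dataDir optional directory with a written dataset
#'   ([writeFeatureDataset()] layout for feature mode, class subfolders for
#'   image mode).
#' @param graphCfg a [graphBuildConfig()].
#' @param trainCfg a [trainConfig()] shared by both models.
#' @param fusionCfg a [fusionConfig()].
#' @param augCfg an [augmentConfig()] or `NULL`; image mode only.
#' @param kFolds number of cross-validation folds (default 5).
#' @param stratified stratify the folds by class.
#' @param innerFrac fraction of each training fold held out (stratified) to
#'   select the fusion weight / train meta-learners; the outer test fold is
#'   never used for selection.
#' @param extraMetrics also report precision, recall, specificity, AUC and
#'   MCC per fold.
#' @param globalSeed master seed.
#' @param outputDir optional directory for summary JSON / CSV artifacts.
#' @return A validated `experimentConfig` list.
#' @export
experimentConfig <- function(spec = syntheticSpec(),
                             mode = c("features", "images"),
                             dataDir = NULL,
                             graphCfg = graphBuildConfig(),
                             trainCfg = trainConfig(),
                             fusionCfg = fusionConfig(),
                             augCfg = NULL,
                             kFolds = 5L, stratified = TRUE,
                             innerFrac = 0.1, extraMetrics = FALSE,
                             globalSeed = 1L, outputDir = NULL) {
  mode <- match.arg(mode)
  innerFrac <- checkNumber(innerFrac, "innerFrac", 0.01, 0.5)
  g <- checkCount(globalSeed, "globalSeed", min = 0L)
  ## stage-offset seed derivation: one integer reproduces the run
  spec$seed <- g
  graphCfg$kmeansSeed <- g + 1001L
  structure(list(
    spec = spec, mode = mode, dataDir = dataDir, graphCfg = graphCfg,
    trainCfg = trainCfg, fusionCfg = fusionCfg, augCfg = augCfg,
    kFolds = checkCount(kFolds, "kFolds", 2L), stratified = isTRUE(stratified),
    innerFrac = innerFrac, extraMetrics = isTRUE(extraMetrics),
    globalSeed = g, outputDir = outputDir,
    seeds = list(data = g, kmeans = g + 1001L, gatInit = g + 2002L,
                 gatTrain = g + 3003L, baseline = g + 4004L,
                 folds = g + 5005L, fusion = g + 6006L, inner = g + 7007L)),
    class = "experimentConfig")
}

loadExperimentData <- function(cfg) {
  if (!is.null(cfg$dataDir)) {
    if (cfg$mode == "features") {
      ds <- readFeatureDataset(cfg$dataDir)
      return(list(features = ds$features, labels = ds$labels))
    }
    ds <- readImageFolder(cfg$dataDir)
    return(list(images = ds$images, labels = ds$labels))
  }
  if (cfg$mode == "features") {
    ds <- generateFeatureDataset(cfg$spec)
    list(features = ds$features, labels = ds$labels)
  } else {
    ds <- generateImageDataset(cfg$spec)
    list(images = ds$images, labels = ds$labels)
  }
}

#' Run the cross-validated experiment
#'
#' For each fold: both models are trained on the inner-train part of the
#' training fold, the inner holdout selects the fusion weight (or trains
#' the meta-learner), and graph model, baseline and fused predictions are
#' evaluated on the untouched test fold. Metrics are summarised across
#' folds as mean, standard deviation and Student-t confidence interval, on
#' the percent scale.
#'
#' @param cfg an [experimentConfig()].
#' @param data optional pre-loaded dataset (as returned by the internal
#'   loader); used by [ablationSweep()] to reuse one generated dataset
#'   across settings.
#' @return A `cvExperiment` object: `summaries` (data frame with one row
#'   per model and metric), `summaryObjects` (list of
#'   [CVSummary-class]), `perFold`, `chosenWeights`, `meanEdges` (average
#'   directed edge count per graph), `configHash` and `config`.
#' @export
runCVExperiment <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "experimentConfig"))
  if (is.null(data)) data <- loadExperimentData(cfg)
  labels <- as.integer(data$labels)
  nClasses <- length(unique(labels))

  if (cfg$mode == "images") {
    pre <- lapply(data$images, preprocessImage)
    extractor <- toyExtractor()
    featureList <- lapply(pre, extractFeatures, extractor = extractor)
  } else {
    featureList <- data$features
  }
  inDim <- ncol(features(featureList[[1]]))
  graphs <- buildGraphs(featureList, cfg$graphCfg, labels)
  meanEdges <- mean(vapply(graphs, function(g) nrow(graphEdges(g)), 1L))

  folds <- stratifiedKFold(labels, k = cfg$kFolds, seed = cfg$seeds$folds,
                           stratified = cfg$stratified)
  metricNames <- if (cfg$extraMetrics)
    c("macro_f1", "balanced_accuracy", "precision", "recall",
      "specificity", "auc", "mcc")
  else c("macro_f1", "balanced_accuracy")

  perFold <- list()
  weights <- numeric(cfg$kFolds)
  for (f in seq_len(cfg$kFolds)) {
    trainIdx <- which(folds != f)
    testIdx <- which(folds == f)
    innerK <- max(2L, round(1 / cfg$innerFrac))
    innerFolds <- stratifiedKFold(labels[trainIdx], k = innerK,
                                  seed = cfg$seeds$inner + f)
    valIdx <- trainIdx[innerFolds == 1L]
    fitIdx <- trainIdx[innerFolds != 1L]

    gCfg <- gatConfig(inDim = inDim, nClasses = nClasses,
                      initSeed = cfg$seeds$gatInit + f)
    tcG <- cfg$trainCfg
    tcG$seed <- cfg$seeds$gatTrain + f
    gnn <- trainGAT(graphs[fitIdx], gCfg, tcG)

    tcB <- cfg$trainCfg
    tcB$seed <- cfg$seeds$baseline + f
    if (cfg$mode == "features") {
      backbone <- meanPoolBackbone(inDim)
      baseTrain <- featureList
      baseline <- finetuneBaseline(baseTrain[fitIdx], labels[fitIdx],
                                   backbone, nClasses, tcB)
    } else {
      backbone <- toyConvBackbone(seed = cfg$seeds$baseline)
      baseTrain <- pre
      baseline <- finetuneBaseline(baseTrain[fitIdx], labels[fitIdx],
                                   backbone, nClasses, tcB, cfg$augCfg)
    }

    pGnnVal <- predictProba(gnn, graphs[valIdx])
    pBaseVal <- predictProba(baseline, baseTrain[valIdx])
    pGnnTest <- predictProba(gnn, graphs[testIdx])
    pBaseTest <- predictProba(baseline, baseTrain[testIdx])

    fCfg <- cfg$fusionCfg
    fCfg$seed <- cfg$seeds$fusion + f
    fus <- fusePredictions(pGnnVal, pBaseVal, labels[valIdx],
                           pGnnTest, pBaseTest, fCfg, cfg$trainCfg)
    weights[f] <- fus$chosenWeight

    preds <- list(gnn = pGnnTest, baseline = pBaseTest, fused = fus$fused)
    for (mod in names(preds)) {
      met <- evalMetrics(labels[testIdx], preds[[mod]])
      for (mn in metricNames)
        perFold[[length(perFold) + 1L]] <-
          data.frame(fold = f, model = mod, metric = mn,
                     value = 100 * met[[mn]])
    }
  }
  perFold <- do.call(rbind, perFold)

  summaryObjects <- list()
  rows <- list()
  for (mod in unique(perFold$model)) {
    for (mn in metricNames) {
      v <- perFold$value[perFold$model == mod & perFold$metric == mn]
      s <- cvSummary(v, metric = mn, model = mod)
      summaryObjects[[paste(mod, mn, sep = ".")]] <- s
      rows[[length(rows) + 1L]] <-
        data.frame(model = mod, metric = mn, mean = s@mean, sd = s@sd,
                   ciLow = s@ciLow, ciHigh = s@ciHigh)
    }
  }
  summaries <- do.call(rbind, rows)

  hash <- configHash(cfg[setdiff(names(cfg), c("outputDir"))])
  result <- structure(list(summaries = summaries,
                           summaryObjects = summaryObjects,
                           perFold = perFold, chosenWeights = weights,
                           meanEdges = meanEdges, configHash = hash,
                           config = cfg),
                      class = "cvExperiment")
  if (!is.null(cfg$outputDir)) writeExperiment(result, cfg$outputDir)
  result
}

writeExperiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    configHash = result$configHash,
    chosenWeights = result$chosenWeights,
    meanEdges = result$meanEdges,
    summaries = lapply(result$summaryObjects, function(s)
      list(model = s@model, metric = s@metric, mean = s@mean, sd = s@sd,
           ciLow = s@ciLow, ciHigh = s@ciHigh, perFold = s@perFold)))
  jsonlite::write_json(payload, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  write.csv(result$perFold, file.path(dir, "per_fold.csv"),
            row.names = FALSE)
  write.csv(data.frame(fold = seq_along(result$chosenWeights),
                       weight = result$chosenWeights),
            file.path(dir, "fusion_weights.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.cvExperiment <- function(x, ...) {
  cat(sprintf("cvExperiment (%d folds, hash %s)\n",
              x$config$kFolds, substr(x$configHash, 1, 8)))
  for (s in x$summaryObjects)
    cat(sprintf("  %-9s %-18s %6.2f (+/- %.2f)  CI [%.2f, %.2f]\n",
                s@model, s@metric, s@mean, s@sd, s@ciLow, s@ciHigh))
  invisible(x)
}

#' Ablation sweep over a graph-construction parameter
#'
#' Re-runs the full cross-validated experiment for each value of the number
#' of clusters or the similarity threshold (the method's two ablation
#' axes), reusing the generated dataset and feature matrices across runs.
#'
#' @param cfg an [experimentConfig()].
#' @param parameter `"nClusters"` or `"similarityThreshold"`.
#' @param values numeric vector of settings.
#' @return A data frame with one row per value, model and metric, plus the
#'   mean directed edge count per graph for each setting.
#' @export
ablationSweep <- function(cfg, parameter = c("nClusters",
                                             "similarityThreshold"),
                          values) {
  parameter <- match.arg(parameter)
  data <- loadExperimentData(cfg)
  out <- list()
  for (v in values) {
    cfgV <- cfg
    cfgV$graphCfg[[parameter]] <- if (parameter == "nClusters")
      checkCount(v, "nClusters") else checkNumber(v, "similarityThreshold",
                                                  -1, 1)
    cfgV$outputDir <- if (!is.null(cfg$outputDir))
      file.path(cfg$outputDir, paste0(parameter, "_", v)) else NULL
    res <- runCVExperiment(cfgV, data = data)
    s <- res$summaries
    s[[parameter]] <- v
    s$meanEdges <- res$meanEdges
    out[[length(out) + 1L]] <- s
  }
  do.call(rbind, out)
}
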