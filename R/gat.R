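#' Graph attention classifier configuration
#'
#' Architecture of the lightweight two-layer graph attention classifier: the
#' first attention layer has four heads of eight features each (32 per node
#' after concatenation), the second four heads of four features (16 per
#' node); each layer is followed by ReLU, then global mean pooling and a
#' linear layer map the graph representation to the number of classes.
#' Attention is the standard additive formulation: per-edge scores pass
#' through a LeakyReLU (negative slope `attentionSlope`) and are softmax
#' normalised over each node's incoming neighbours.
#'
#' @param inDim width of the node (centroid) feature vectors.
#' @param nClasses number of output classes.
#' @param layer1Heads,layer1PerHead heads and per-head width of layer 1
#'   (defaults 4 and 8; concatenated width 32).
#' @param layer2Heads,layer2PerHead heads and per-head width of layer 2
#'   (defaults 4 and 4; concatenated width 16).
#' @param addSelfLoops add self-loop edges inside the attention layers so
#'   isolated nodes (possible when no similarity exceeds the edge threshold)
#'   still have a well-defined neighbourhood. Default `TRUE`.
#' @param attentionSlope LeakyReLU negative slope for attention scores.
#' @param initSeed seed of the Glorot parameter initialisation.
#' @return A validated `gatConfig` list.
#' @export
gatConfig <- function(inDim, nClasses, layer1Heads = 4L, layer1PerHead = 8L,
                      layer2Heads = 4L, layer2PerHead = 4L,
                      addSelfLoops = TRUE, attentionSlope = 0.2,
                      initSeed = 1L) {
  structure(list(
    inDim = checkCount(inDim, "inDim"),
    nClasses = checkCount(nClasses, "nClasses", 2L),
    layer1Heads = checkCount(layer1Heads, "layer1Heads"),
    layer1PerHead = checkCount(layer1PerHead, "layer1PerHead"),
    layer2Heads = checkCount(layer2Heads, "layer2Heads"),
    layer2PerHead = checkCount(layer2PerHead, "layer2PerHead"),
    addSelfLoops = isTRUE(addSelfLoops),
    attentionSlope = checkNumber(attentionSlope, "attentionSlope", 0, 10),
    initSeed = checkCount(initSeed, "initSeed", min = -.Machine$integer.max)),
    class = "gatConfig")
}

#' Optimisation configuration
#'
#' The training protocol shared by the graph classifier, the baseline
#' fine-tuning and the stacked meta-learners: Adam with learning rate 1e-4,
#' 300 epochs, mini-batches of 32, cross-entropy loss, and a fixed seed for
#' initialisation and shuffling.
#'
#' @param learningRate Adam learning rate (> 0).
#' @param epochs number of epochs (>= 1).
#' @param batchSize mini-batch size.
#' @param seed seed controlling shuffling (and initialisation where a model
#'   has no separate init seed).
#' @return A validated `trainConfig` list.
#' @export
trainConfig <- function(learningRate = 1e-4, epochs = 300L, batchSize = 32L,
                        seed = 1L) {
  lr <- checkNumber(learningRate, "learningRate", min = 0)
  if (lr <= 0) stop("learningRate must be > 0", call. = FALSE)
  structure(list(
    learningRate = lr,
    epochs = checkCount(epochs, "epochs"),
    batchSize = checkCount(batchSize, "batchSize"),
    seed = checkCount(seed, "seed", min = -.Machine$integer.max)),
    class = "trainConfig")
}

#' Initialise graph attention parameters
#'
#' Glorot-uniform initialisation of all weights (biases zero), deterministic
#' under the config's `initSeed`.
#'
#' @param config a [gatConfig()].
#' @return Named list of parameter matrices.
#' @export
initGATParams <- function(config) {
  stopifnot(inherits(config, "gatConfig"))
  p1 <- config$layer1Heads * config$layer1PerHead
  p2 <- config$layer2Heads * config$layer2PerHead
  withSeed(config$initSeed, list(
    W1 = glorotMatrix(config$inDim, p1),
    a1_src = glorotMatrix(config$layer1PerHead, config$layer1Heads),
    a1_dst = glorotMatrix(config$layer1PerHead, config$layer1Heads),
    b1 = matrix(0, p1, 1),
    W2 = glorotMatrix(p1, p2),
    a2_src = glorotMatrix(config$layer2PerHead, config$layer2Heads),
    a2_dst = glorotMatrix(config$layer2PerHead, config$layer2Heads),
    b2 = matrix(0, p2, 1),
    W_out = glorotMatrix(p2, config$nClasses),
    b_out = matrix(0, config$nClasses, 1)))
}

## Concatenate a list of ImageGraphs into the flat arrays the compiled code
## consumes: stacked node features, 0-based node offsets, concatenated local
## 0-based edges and edge offsets.
graphsToBatch <- function(graphs, inDim) {
  sizes <- vapply(graphs, function(g) nrow(nodeFeatures(g)), 1L)
  dims <- vapply(graphs, function(g) ncol(nodeFeatures(g)), 1L)
  if (any(dims != inDim))
    stop(sprintf("graph node features have width %d but the model expects %d",
                 dims[which(dims != inDim)[1]], inDim), call. = FALSE)
  Xall <- do.call(rbind, lapply(graphs, nodeFeatures))
  nodePtr <- c(0L, cumsum(sizes))
  edgeList <- lapply(graphs, function(g) graphEdges(g) - 1L)
  eSizes <- vapply(edgeList, nrow, 1L)
  edges <- do.call(rbind, edgeList)
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- matrix(integer(0), 0, 2)
  storage.mode(edges) <- "integer"
  list(X = Xall, nodePtr = as.integer(nodePtr), edges = edges,
       edgePtr = as.integer(c(0L, cumsum(eSizes))))
}

#' Forward pass of the graph attention classifier
#'
#' Computes the classifier logits for a list of graphs. With
#' `returnIntermediates = TRUE` also returns the per-node representations
#' after each attention layer (widths 32 and 16 under the default
#' architecture) and the pooled graph vectors.
#'
#' @param model a trained `gatModel` from [trainGAT()], or a list with
#'   elements `params` and `config` (e.g. freshly initialised parameters).
#' @param graphs list of [ImageGraph-class].
#' @param returnIntermediates return hidden representations as well.
#' @return An `n_graphs x n_classes` logit matrix, or a list with `logits`,
#'   `h1`, `h2`, `pooled`.
#' @export
gatForward <- function(model, graphs, returnIntermediates = FALSE) {
  cfg <- model$config
  stopifnot(inherits(cfg, "gatConfig"))
  if (is(graphs, "ImageGraph")) graphs <- list(graphs)
  b <- graphsToBatch(graphs, cfg$inDim)
  out <- gat_forward_cpp(model$params, b$X, b$nodePtr, b$edges, b$edgePtr,
                         cfg$layer1Heads, cfg$layer1PerHead,
                         cfg$layer2Heads, cfg$layer2PerHead,
                         cfg$attentionSlope, cfg$addSelfLoops,
                         returnIntermediates)
  if (returnIntermediates) out else out$logits
}

#' Train the graph attention classifier
#'
#' Mini-batch Adam training with cross-entropy loss. Graphs are shuffled
#' each epoch with a seeded, fully specified scheme, so two runs with the
#' same configuration produce identical parameters. Training runs in single
#' precision (the deep-learning standard); returned parameters and all
#' predictions are double.
#'
#' @param graphs list of labeled [ImageGraph-class].
#' @param gatCfg a [gatConfig()]; `inDim` must match the graphs' node
#'   feature width.
#' @param tc a [trainConfig()].
#' @param labels optional 0-based labels overriding the graphs' own.
#' @return A `gatModel`: list with `params`, `config`, `trainConfig` and
#'   per-epoch `lossHistory`.
#' @export
trainGAT <- function(graphs, gatCfg, tc = trainConfig(), labels = NULL) {
  stopifnot(inherits(gatCfg, "gatConfig"), inherits(tc, "trainConfig"))
  if (is.null(labels))
    labels <- vapply(graphs, imageLabel, 1L)
  if (anyNA(labels))
    stop("all training graphs must be labeled", call. = FALSE)
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= gatCfg$nClasses))
    stop("labels must lie in 0..nClasses-1", call. = FALSE)
  if (length(unique(labels)) < gatCfg$nClasses)
    stop("every class must appear at least once in the training set",
         call. = FALSE)
  params <- initGATParams(gatCfg)
  b <- graphsToBatch(graphs, gatCfg$inDim)
  fit <- gat_train_cpp(params, b$X, b$nodePtr, b$edges, b$edgePtr,
                       labels, gatCfg$layer1Heads, gatCfg$layer1PerHead,
                       gatCfg$layer2Heads, gatCfg$layer2PerHead,
                       gatCfg$attentionSlope, gatCfg$addSelfLoops,
                       tc$learningRate, tc$epochs, tc$batchSize, tc$seed)
  structure(list(params = fit$params, config = gatCfg, trainConfig = tc,
                 lossHistory = as.numeric(fit$lossHistory)),
            class = "gatModel")
}

#' @export
print.gatModel <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "gatModel: %d -> %d (%d heads x %d) -> %d (%d heads x %d) -> %d classes\n",
    cfg$inDim, cfg$layer1Heads * cfg$layer1PerHead, cfg$layer1Heads,
    cfg$layer1PerHead, cfg$layer2Heads * cfg$layer2PerHead, cfg$layer2Heads,
    cfg$layer2PerHead, cfg$nClasses))
  if (length(x$lossHistory))
    cat(sprintf("trained %d epochs; loss %.4f -> %.4f\n",
                length(x$lossHistory), x$lossHistory[1],
                x$lossHistory[length(x$lossHistory)]))
  invisible(x)
}

#' Class-probability predictions
#'
#' Generic returning a [ProbabilityMatrix-class] (softmax rows, one per
#' input sample, ordered as the inputs) from a trained model.
#'
#' @param object a trained model (`gatModel`, `baselineModel`, `metaModel`).
#' @param newdata input samples appropriate for the model.
#' @param ... passed to methods.
#' @return A [ProbabilityMatrix-class].
#' @export
predictProba <- function(object, newdata, ...) UseMethod("predictProba")

#' @rdname predictProba
#' @export
predictProba.gatModel <- function(object, newdata, ...) {
  if (is(newdata, "ImageGraph")) newdata <- list(newdata)
  logits <- gatForward(object, newdata)
  ProbabilityMatrix(softmaxRows(logits),
                    sampleIds = vapply(newdata, imageId, ""))
}

#' Save / load a trained graph attention model as JSON
#'
#' Plain-text checkpoint with the architecture config embedded, so a loaded
#' model predicts identically to the saved one.
#'
#' @param model a `gatModel`.
#' @param path file path.
#' @return `loadGATModel` returns the reconstructed `gatModel`.
#' @export
saveGATModel <- function(model, path) {
  stopifnot(inherits(model, "gatModel"))
  payload <- list(config = unclass(model$config),
                  trainConfig = unclass(model$trainConfig),
                  lossHistory = model$lossHistory,
                  params = model$params)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveGATModel
#' @export
loadGATModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(gatConfig, payload$config[c(
    "inDim", "nClasses", "layer1Heads", "layer1PerHead", "layer2Heads",
    "layer2PerHead", "addSelfLoops", "attentionSlope", "initSeed")])
  tc <- do.call(trainConfig, payload$trainConfig[c(
    "learningRate", "epochs", "batchSize", "seed")])
  params <- lapply(payload$params, function(p) {
    m <- as.matrix(p)
    dimnames(m) <- NULL
    m
  })
  structure(list(params = params, config = cfg, trainConfig = tc,
                 lossHistory = as.numeric(payload$lossHistory)),
            class = "gatModel")
}
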