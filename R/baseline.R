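#' Data augmentation configuration
#'
#' Random horizontal/vertical flips and random rotations applied during
#' fine-tuning (never at prediction time). Rotations default to the four
#' right angles, which are exact index remaps with no interpolation or
#' padding artifacts; arbitrary angles are supported via bilinear rotation.
#'
#' @param horizontalFlip,verticalFlip flip probabilities in `[0, 1]`.
#' @param rotationSet numeric set of angles (degrees); one is drawn
#'   uniformly per image.
#' @param seed seed used when the caller does not manage the RNG itself.
#' @return A validated `augmentConfig` list.
#' @export
augmentConfig <- function(horizontalFlip = 0.5, verticalFlip = 0.5,
                          rotationSet = c(0, 90, 180, 270), seed = 1L) {
  structure(list(
    horizontalFlip = checkNumber(horizontalFlip, "horizontalFlip", 0, 1),
    verticalFlip = checkNumber(verticalFlip, "verticalFlip", 0, 1),
    rotationSet = as.numeric(rotationSet),
    seed = checkCount(seed, "seed", min = -.Machine$integer.max)),
    class = "augmentConfig")
}

## Exact 90-degree clockwise rotation of an H x W x 3 array:
## pixel (r, c) moves to (c, H + 1 - r).
rotate90cw <- function(px) {
  d <- dim(px)
  out <- array(0, c(d[2], d[1], 3))
  for (ch in 1:3)
    out[, , ch] <- t(px[d[1]:1, , ch, drop = TRUE])
  out
}

#' Augment one image
#'
#' Applies an independent horizontal flip, an independent vertical flip and
#' one rotation drawn uniformly from the rotation set, consuming draws from
#' the current RNG (callers seed the RNG to control reproducibility). The
#' label is unchanged. Right-angle rotations are exact; other angles use
#' bilinear interpolation at fixed output size.
#'
#' @param image an [ImageRecord-class].
#' @param cfg an [augmentConfig()].
#' @return The augmented [ImageRecord-class].
#' @export
augmentImage <- function(image, cfg) {
  stopifnot(is(image, "ImageRecord"), inherits(cfg, "augmentConfig"))
  px <- pixels(image)
  if (runif(1) < cfg$horizontalFlip)
    px <- px[, dim(px)[2]:1, , drop = FALSE]
  if (runif(1) < cfg$verticalFlip)
    px <- px[dim(px)[1]:1, , , drop = FALSE]
  angle <- cfg$rotationSet[sample.int(length(cfg$rotationSet), 1L)]
  a <- angle %% 360
  if (a %% 90 == 0) {
    for (i in seq_len((a %/% 90) %% 4)) px <- rotate90cw(px)
  } else {
    d <- dim(px)
    ebi <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
    ebi <- EBImage::rotate(ebi, a, output.dim = c(d[2], d[1]))
    px <- pmin(pmax(aperm(EBImage::imageData(ebi), c(2, 1, 3)), 0), 1)
  }
  ImageRecord(px, imageId = imageId(image), label = imageLabel(image))
}

#' Pluggable backbone contract for baseline fine-tuning
#'
#' A backbone embeds one standardized image (or one patch-feature matrix)
#' into a fixed-width feature vector; fine-tuning replaces the original
#' classification layers with a single linear head of width `nClasses`.
#' Generic adapters are used frozen (only the head trains); the built-in
#' [toyConvBackbone()] supports full end-to-end training.
#'
#' @param name backbone name.
#' @param embed `function(sample)` returning a numeric vector of length
#'   `dim`.
#' @param dim embedding width.
#' @param trainable whether backbone weights update during fine-tuning.
#' @return A `backboneAdapter` object.
#' @export
backboneAdapter <- function(name, embed, dim, trainable = FALSE) {
  stopifnot(is.function(embed))
  structure(list(name = as.character(name), embed = embed,
                 dim = checkCount(dim, "dim"), trainable = isTRUE(trainable)),
            class = "backboneAdapter")
}

#' Identity backbone: flattened pixels
#'
#' Embeds an image as its flattened pixel vector. With augmentation disabled
#' this makes fine-tuning exactly multinomial logistic regression on raw
#' pixels, a useful sanity anchor.
#'
#' @param imageSize,channels expected input geometry.
#' @return A frozen [backboneAdapter()].
#' @export
identityBackbone <- function(imageSize = 32L, channels = 3L) {
  d <- checkCount(imageSize, "imageSize")^2 * checkCount(channels, "channels")
  backboneAdapter("identity",
                  function(img) as.numeric(pixels(img)), d,
                  trainable = FALSE)
}

#' Mean-pooling backbone over patch features
#'
#' Embeds a [PatchFeatureMatrix-class] as the mean of its patch rows. This
#' is the baseline counterpart used when the pipeline runs on precomputed
#' feature datasets, where no raw pixels exist to fine-tune on.
#'
#' @param dim feature width of the patch matrices.
#' @return A frozen [backboneAdapter()].
#' @export
meanPoolBackbone <- function(dim) {
  backboneAdapter("meanpool",
                  function(pfm) colMeans(features(pfm)),
                  dim, trainable = FALSE)
}

#' Small trainable convolutional test backbone
#'
#' A seeded patch-embedding convolution (kernel = stride = `patchSize`)
#' followed by ReLU and global average pooling over patch positions. Being a
#' single linear map per patch, its gradients are exact and cheap, which
#' makes full end-to-end fine-tuning possible without a deep-learning
#' framework. Random init; intended as the test double for real pretrained
#' backbones, which plug in via [backboneAdapter()].
#'
#' @param nFilters embedding width (default 32).
#' @param patchSize convolution kernel/stride in pixels.
#' @param seed weight initialisation seed.
#' @param trainable update backbone weights during fine-tuning.
#' @return A `backboneAdapter` with conv weights attached.
#' @export
toyConvBackbone <- function(nFilters = 32L, patchSize = 32L, seed = 7L,
                            trainable = TRUE) {
  nFilters <- checkCount(nFilters, "nFilters")
  patchSize <- checkCount(patchSize, "patchSize")
  pdim <- 3L * patchSize^2
  weights <- withSeed(seed, list(Wc = glorotMatrix(pdim, nFilters),
                                 bc = numeric(nFilters)))
  bb <- backboneAdapter("toyconv", embed = function(img) {
    M <- imageToPatchMatrix(pixels(img), patchSize)
    colMeans(pmax(sweep(M %*% weights$Wc, 2L, weights$bc, "+"), 0))
  }, dim = nFilters, trainable = trainable)
  bb$patchSize <- patchSize
  bb$weights <- weights
  class(bb) <- c("hgfConvBackbone", class(bb))
  bb
}

## Row-major patch flattening: one row per patch position, pixels of the
## patch flattened channel-last.
imageToPatchMatrix <- function(px, patchSize) {
  g <- patchGridShape(dim(px)[1], patchSize)
  M <- matrix(0, prod(g), 3L * patchSize^2)
  idx <- 1L
  for (r in seq_len(g[1])) {
    rows <- ((r - 1L) * patchSize + 1L):(r * patchSize)
    for (c in seq_len(g[2])) {
      cols <- ((c - 1L) * patchSize + 1L):(c * patchSize)
      M[idx, ] <- as.numeric(px[rows, cols, , drop = FALSE])
      idx <- idx + 1L
    }
  }
  M
}

embedAll <- function(backbone, samples) {
  t(vapply(samples, backbone$embed, numeric(backbone$dim)))
}

#' Fine-tune a baseline model
#'
#' Trains a linear classification head of width `nClasses` on top of a
#' backbone with Adam and cross-entropy (mini-batches, seeded shuffling).
#' For the built-in trainable conv backbone the backbone weights update
#' jointly with the head; generic adapters stay frozen and only the head
#' trains. When an [augmentConfig()] is given and the inputs are images,
#' each image is re-augmented every epoch during training; prediction never
#' augments.
#'
#' @param x list of [ImageRecord-class] (or [PatchFeatureMatrix-class] for
#'   feature-space backbones such as [meanPoolBackbone()]).
#' @param labels 0-based integer labels.
#' @param backbone a [backboneAdapter()].
#' @param nClasses number of classes (head width).
#' @param tc a [trainConfig()].
#' @param augCfg optional [augmentConfig()]; images only.
#' @return A `baselineModel` with per-epoch `lossHistory`.
#' @export
finetuneBaseline <- function(x, labels, backbone, nClasses,
                             tc = trainConfig(), augCfg = NULL) {
  stopifnot(inherits(backbone, "backboneAdapter"), inherits(tc, "trainConfig"))
  nClasses <- checkCount(nClasses, "nClasses", 2L)
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= nClasses))
    stop("labels must lie in 0..nClasses-1", call. = FALSE)
  if (length(unique(labels)) < nClasses)
    stop("every class must appear in the training set", call. = FALSE)
  isImages <- is(x[[1]], "ImageRecord")
  if (!is.null(augCfg) && !isImages)
    stop("augmentation applies to images only", call. = FALSE)

  if (inherits(backbone, "hgfConvBackbone") && backbone$trainable) {
    model <- trainConvJoint(x, labels, backbone, nClasses, tc, augCfg)
  } else {
    if (is.null(augCfg)) {
      X <- embedAll(backbone, x)
      mlp <- mlpTrain(X, labels, nClasses, hidden = integer(0),
                      lr = tc$learningRate, epochs = tc$epochs,
                      batchSize = tc$batchSize, seed = tc$seed)
      model <- list(type = "head", mlp = mlp, lossHistory = mlp$lossHistory)
    } else {
      model <- trainHeadAugmented(x, labels, backbone, nClasses, tc, augCfg)
    }
  }
  structure(c(model, list(backbone = backbone, nClasses = nClasses)),
            class = "baselineModel")
}

## Head-only training with per-epoch augmentation (frozen backbone).
trainHeadAugmented <- function(images, y, backbone, nClasses, tc, augCfg) {
  layers <- mlpInit(backbone$dim, integer(0), nClasses, tc$seed)
  flat <- flattenLayers(layers)
  state <- list(t = 0L, m = lapply(flat, function(p) p * 0),
                v = lapply(flat, function(p) p * 0))
  n <- length(images)
  lossHistory <- numeric(tc$epochs)
  withSeed(tc$seed + 1L, {
    for (ep in seq_len(tc$epochs)) {
      Xe <- embedAll(backbone, lapply(images, augmentImage, cfg = augCfg))
      ord <- sample.int(n)
      epLoss <- 0
      for (s in seq(1L, n, by = tc$batchSize)) {
        idx <- ord[s:min(s + tc$batchSize - 1L, n)]
        W <- flat[[1L]]; b <- flat[[2L]]
        logits <- sweep(Xe[idx, , drop = FALSE] %*% W, 2L, b, "+")
        P <- softmaxRows(logits)
        bsz <- length(idx)
        epLoss <- epLoss - sum(log(pmax(P[cbind(seq_len(bsz), y[idx] + 1L)],
                                        1e-12)))
        dZ <- P
        dZ[cbind(seq_len(bsz), y[idx] + 1L)] <-
          dZ[cbind(seq_len(bsz), y[idx] + 1L)] - 1
        dZ <- dZ / bsz
        grads <- list(crossprod(Xe[idx, , drop = FALSE], dZ), colSums(dZ))
        upd <- adamStep(flat, grads, state, tc$learningRate)
        flat <- upd$params; state <- upd$state
      }
      lossHistory[ep] <- epLoss / n
    }
  })
  list(type = "head",
       mlp = structure(list(layers = rebuildLayers(flat),
                            nClasses = nClasses), class = "hgfMlp"),
       lossHistory = lossHistory)
}

## Joint training of the patch-conv backbone and the linear head.
trainConvJoint <- function(images, y, backbone, nClasses, tc, augCfg) {
  ps <- backbone$patchSize
  pdim <- 3L * ps^2
  nf <- backbone$dim
  params <- withSeed(tc$seed, list(
    Wc = backbone$weights$Wc, bc = matrix(backbone$weights$bc, ncol = 1),
    Wh = glorotMatrix(nf, nClasses), bh = matrix(0, nClasses, 1)))
  state <- list(t = 0L, m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- length(images)
  patchesOf <- function(imgs) lapply(imgs, function(im)
    imageToPatchMatrix(pixels(im), ps))
  staticPatches <- if (is.null(augCfg)) patchesOf(images) else NULL
  lossHistory <- numeric(tc$epochs)
  withSeed(tc$seed + 1L, {
    for (ep in seq_len(tc$epochs)) {
      patches <- if (is.null(augCfg)) staticPatches else
        patchesOf(lapply(images, augmentImage, cfg = augCfg))
      nPatch <- nrow(patches[[1]])
      ord <- sample.int(n)
      epLoss <- 0
      for (s in seq(1L, n, by = tc$batchSize)) {
        idx <- ord[s:min(s + tc$batchSize - 1L, n)]
        bsz <- length(idx)
        M <- do.call(rbind, patches[idx])              # (bsz*nPatch) x pdim
        A <- pmax(sweep(M %*% params$Wc, 2L, params$bc[, 1], "+"), 0)
        G <- matrix(0, bsz, nf)                        # pooled embeddings
        for (i in seq_len(bsz))
          G[i, ] <- colMeans(A[((i - 1L) * nPatch + 1L):(i * nPatch), ,
                               drop = FALSE])
        logits <- sweep(G %*% params$Wh, 2L, params$bh[, 1], "+")
        P <- softmaxRows(logits)
        epLoss <- epLoss - sum(log(pmax(P[cbind(seq_len(bsz), y[idx] + 1L)],
                                        1e-12)))
        dZ <- P
        dZ[cbind(seq_len(bsz), y[idx] + 1L)] <-
          dZ[cbind(seq_len(bsz), y[idx] + 1L)] - 1
        dZ <- dZ / bsz
        dWh <- crossprod(G, dZ)
        dbh <- matrix(colSums(dZ), ncol = 1)
        dG <- tcrossprod(dZ, params$Wh)
        dA <- dG[rep(seq_len(bsz), each = nPatch), , drop = FALSE] / nPatch
        dA <- dA * (A > 0)
        grads <- list(Wc = crossprod(M, dA),
                      bc = matrix(colSums(dA), ncol = 1),
                      Wh = dWh, bh = dbh)
        upd <- adamStep(params, grads, state, tc$learningRate)
        params <- upd$params; state <- upd$state
      }
      lossHistory[ep] <- epLoss / n
    }
  })
  list(type = "conv", params = params, patchSize = ps,
       lossHistory = lossHistory)
}

#' @rdname predictProba
#' @export
predictProba.baselineModel <- function(object, newdata, ...) {
  ids <- vapply(newdata, function(s)
    if (is(s, "ImageRecord") || is(s, "PatchFeatureMatrix")) imageId(s)
    else "sample", "")
  P <- if (object$type == "conv") {
    ps <- object$patchSize
    logits <- t(vapply(newdata, function(im) {
      M <- imageToPatchMatrix(pixels(im), ps)
      A <- pmax(sweep(M %*% object$params$Wc, 2L, object$params$bc[, 1],
                      "+"), 0)
      g <- colMeans(A)
      as.numeric(g %*% object$params$Wh + object$params$bh[, 1])
    }, numeric(object$nClasses)))
    softmaxRows(logits)
  } else {
    X <- embedAll(object$backbone, newdata)
    mlpPredictProba(object$mlp, X)
  }
  ProbabilityMatrix(P, sampleIds = ids)
}

#' @export
print.baselineModel <- function(x, ...) {
  cat(sprintf("baselineModel: backbone '%s' (%s), %d classes\n",
              x$backbone$name,
              if (x$type == "conv") "fine-tuned end-to-end"
              else "frozen, linear head",
              x$nClasses))
  if (length(x$lossHistory))
    cat(sprintf("trained %d epochs; loss %.4f -> %.4f\n",
                length(x$lossHistory), x$lossHistory[1],
                x$lossHistory[length(x$lossHistory)]))
  invisible(x)
}
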