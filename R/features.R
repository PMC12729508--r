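#' ImageNet channel statistics
#'
#' Community-standard ImageNet channel means and standard deviations used to
#' standardize RGB images before feature extraction. Overridable in
#' [preprocessImage()].
#' @export
imagenetMeans <- c(0.485, 0.456, 0.406)

#' @rdname imagenetMeans
#' @export
imagenetSds <- c(0.229, 0.224, 0.225)

#' Resize and channel-standardize an image
#'
#' Resizes an RGB image to `targetSize x targetSize` pixels (bilinear, via
#' EBImage) and standardizes each channel as `(x - mean) / sd` with the
#' ImageNet statistics by default.
#'
#' @param image an [ImageRecord-class].
#' @param targetSize output side length in pixels (default 224).
#' @param channelMeans,channelSds length-3 numeric channel statistics.
#' @return An [ImageRecord-class] of size `targetSize x targetSize x 3` whose
#'   channels are standardized (values are no longer restricted to `[0, 1]`).
#' @examples
#' img <- ImageRecord(array(0.5, c(32, 32, 3)), "x")
#' out <- preprocessImage(img, 224, channelMeans = rep(0.5, 3),
#'                        channelSds = rep(1, 3))
#' all(pixels(out) == 0)
#' @export
preprocessImage <- function(image, targetSize = 224L,
                            channelMeans = imagenetMeans,
                            channelSds = imagenetSds) {
  stopifnot(is(image, "ImageRecord"))
  targetSize <- checkCount(targetSize, "targetSize")
  if (length(channelMeans) != 3L || length(channelSds) != 3L)
    stop("channelMeans and channelSds must have length 3", call. = FALSE)
  if (any(channelSds == 0))
    stop("channelSds must be nonzero", call. = FALSE)
  px <- pixels(image)
  if (any(dim(px)[1:2] != targetSize)) {
    ebi <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
    ebi <- EBImage::resize(ebi, w = targetSize, h = targetSize)
    px <- aperm(EBImage::imageData(ebi), c(2, 1, 3))
  }
  for (ch in 1:3)
    px[, , ch] <- (px[, , ch] - channelMeans[ch]) / channelSds[ch]
  ImageRecord(px, imageId = imageId(image), label = imageLabel(image))
}

#' Patch grid shape for non-overlapping patches
#'
#' Number of patch rows and columns obtained when tiling a square image with
#' non-overlapping square patches: `rows = cols = floor(imageSize /
#' patchSize)`. At 224 px this reproduces the standard token grids: patch 32
#' gives `7 x 7` (49 patches), patch 16 gives `14 x 14` (196), patch 14 gives
#' `16 x 16` (256).
#'
#' @param imageSize image side length in pixels.
#' @param patchSize patch side length in pixels (`0 < patchSize <=
#'   imageSize`).
#' @return Integer vector `(rows, cols)`.
#' @examples
#' patchGridShape(224, 16)   # 14 x 14
#' @export
patchGridShape <- function(imageSize, patchSize) {
  imageSize <- checkCount(imageSize, "imageSize")
  patchSize <- checkCount(patchSize, "patchSize")
  if (patchSize > imageSize)
    stop("patchSize must not exceed imageSize", call. = FALSE)
  n <- as.integer(imageSize %/% patchSize)
  c(rows = n, cols = n)
}

#' Pluggable patch-feature extractor contract
#'
#' An extractor adapter turns a standardized square image into a
#' [PatchFeatureMatrix-class] whose grid must match
#' `patchGridShape(size, patchSize)`. Pretrained backbones (pathology
#' foundation models, CNNs, ViTs) plug in through this contract by exposing
#' their spatial token grid / final feature-map cells; the package itself
#' ships only a deterministic toy extractor ([toyExtractor()]).
#'
#' @param name extractor name (recorded in outputs).
#' @param patchSize patch side length in pixels.
#' @param featureDim width of each patch embedding.
#' @param apply `function(pixelArray)` returning an `nPatches x featureDim`
#'   matrix in row-major grid order (top-left patch first).
#' @return An `extractorAdapter` object.
#' @export
extractorAdapter <- function(name, patchSize, featureDim, apply) {
  stopifnot(is.function(apply))
  structure(list(name = as.character(name),
                 patchSize = checkCount(patchSize, "patchSize"),
                 featureDim = checkCount(featureDim, "featureDim"),
                 apply = apply),
            class = "extractorAdapter")
}

## Per-patch summary statistics: per-channel mean, sd, and mean absolute
## horizontal/vertical gradient. Depends only on pixels inside the patch.
patchStats <- function(patch) {
  out <- numeric(12L)
  for (ch in 1:3) {
    p <- patch[, , ch]
    out[ch] <- mean(p)
    out[3L + ch] <- sd(as.vector(p))
    out[6L + ch] <- mean(abs(p[, -1L, drop = FALSE] -
                             p[, -ncol(p), drop = FALSE]))
    out[9L + ch] <- mean(abs(p[-1L, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE]))
  }
  out
}

#' Built-in deterministic toy extractor
#'
#' A weightless stand-in for a pretrained backbone used to exercise the
#' pipeline end to end: each patch is summarized by 12 statistics
#' (per-channel mean, sd, horizontal and vertical gradient energy) which are
#' mapped to `featureDim` dimensions by a fixed seeded random projection.
#' The output for a patch depends only on the pixels inside that patch.
#'
#' @param featureDim output embedding width (default 64).
#' @param patchSize patch side length in pixels (default 16).
#' @param seed seed of the fixed random projection.
#' @return An [extractorAdapter()].
#' @export
toyExtractor <- function(featureDim = 64L, patchSize = 16L, seed = 42L) {
  featureDim <- checkCount(featureDim, "featureDim")
  patchSize <- checkCount(patchSize, "patchSize")
  proj <- withSeed(seed,
    matrix(rnorm(12L * featureDim, sd = 1 / sqrt(12)), 12L, featureDim))
  apply_fn <- function(px) {
    size <- dim(px)[1]
    grid <- patchGridShape(size, patchSize)
    rowsOf <- function(r) ((r - 1L) * patchSize + 1L):(r * patchSize)
    S <- matrix(0, prod(grid), 12L)
    idx <- 1L
    for (r in seq_len(grid[1])) {
      for (c in seq_len(grid[2])) {
        S[idx, ] <- patchStats(px[rowsOf(r), rowsOf(c), , drop = FALSE])
        idx <- idx + 1L
      }
    }
    S %*% proj
  }
  extractorAdapter("toy", patchSize, featureDim, apply_fn)
}

#' Extract the patch-feature matrix of one image
#'
#' Applies an extractor adapter to a preprocessed square image and validates
#' the adapter's output contract: the grid must equal
#' `patchGridShape(size, patchSize)` and the embedding width must equal the
#' adapter's stated `featureDim`. Rows are ordered row-major over the grid
#' (top-left patch first).
#'
#' @param image a standardized square [ImageRecord-class] (see
#'   [preprocessImage()]).
#' @param extractor an [extractorAdapter()].
#' @return A [PatchFeatureMatrix-class].
#' @export
extractFeatures <- function(image, extractor) {
  stopifnot(is(image, "ImageRecord"), inherits(extractor, "extractorAdapter"))
  px <- pixels(image)
  if (dim(px)[1] != dim(px)[2])
    stop("extractFeatures expects a square (preprocessed) image",
         call. = FALSE)
  grid <- patchGridShape(dim(px)[1], extractor$patchSize)
  X <- extractor$apply(px)
  if (!is.matrix(X) || nrow(X) != prod(grid) ||
      ncol(X) != extractor$featureDim || !all(is.finite(X)))
    stop(sprintf(
      "extractor '%s' violated its contract: expected %d x %d finite matrix",
      extractor$name, prod(grid), extractor$featureDim), call. = FALSE)
  PatchFeatureMatrix(X, grid, imageId = imageId(image),
                     extractorName = extractor$name)
}

#' Read a class-subfolder image dataset
#'
#' Reads `dir/<class>/<file>.{png,jpg,jpeg,tif,tiff}` trees (the layout
#' written by [writeImageDataset()]). Class subfolders are sorted
#' alphabetically and assigned 0-based labels in that order.
#'
#' @param dir dataset root directory.
#' @return List with `images` (list of [ImageRecord-class]), `labels`
#'   (0-based integers) and `classNames`.
#' @export
readImageFolder <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop("no class subfolders found in ", dir, call. = FALSE)
  images <- list()
  labels <- integer(0)
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(dir, classes[ci]),
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      ebi <- EBImage::readImage(f)
      px <- EBImage::imageData(ebi)
      if (length(dim(px)) == 2L)
        px <- array(rep(px, 3L), c(dim(px), 3L))
      if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
      if (dim(px)[3] != 3L)
        stop("expected an RGB image: ", f, call. = FALSE)
      px <- aperm(px, c(2, 1, 3))
      id <- tools::file_path_sans_ext(basename(f))
      images[[length(images) + 1L]] <-
        ImageRecord(px, imageId = id, label = ci - 1L)
      labels <- c(labels, ci - 1L)
    }
  }
  list(images = images, labels = labels, classNames = classes)
}
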