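#' Specification for a synthetic labeled dataset
#'
#' Describes a synthetic dataset with controllable class structure, used to
#' exercise the full pipeline without external images or pretrained weights.
#' Feature-mode generation draws each image's patch rows from a Gaussian
#' mixture whose component means are shared across classes and shifted by
#' `classSeparation` along a class-specific unit direction; image-mode
#' generation paints class-dependent block textures plus pixel noise.
#'
#' @param nImages total number of images (>= `nClasses`).
#' @param nClasses number of classes, 2 or 4 (binary and four-class tasks).
#' @param patchGrid integer `(rows, cols)` of the emulated token grid; the
#'   default `c(14, 14)` matches a 224 px image with 16 px patches
#'   (196 patches).
#' @param featureDim width of each patch embedding (default 768, the token
#'   width of a ViT-Base-like backbone).
#' @param nComponents latent texture clusters per image (mixture components).
#' @param classSeparation nonnegative distance between class-specific
#'   component means; 0 means no class signal at all.
#' @param noiseSd standard deviation of the isotropic patch noise.
#' @param imageSize side length in pixels for image-mode generation (>= 32).
#' @param seed integer seed; identical specs reproduce identical datasets.
#' @return A validated `syntheticSpec` list.
#' @examples
#' spec <- syntheticSpec(nImages = 8, nClasses = 2, classSeparation = 5)
#' ds <- generateFeatureDataset(spec)
#' table(ds$labels)
#' @export
syntheticSpec <- function(nImages = 200L, nClasses = 2L,
                          patchGrid = c(14L, 14L), featureDim = 768L,
                          nComponents = 5L, classSeparation = 1,
                          noiseSd = 1, imageSize = 64L, seed = 1L) {
  nClasses <- checkCount(nClasses, "nClasses", 2L)
  if (!nClasses %in% c(2L, 4L))
    stop("nClasses must be 2 or 4", call. = FALSE)
  nImages <- checkCount(nImages, "nImages", 1L)
  if (nImages < nClasses)
    stop("nImages must be >= nClasses so every class appears", call. = FALSE)
  if (length(patchGrid) != 2L)
    stop("patchGrid must be (rows, cols)", call. = FALSE)
  patchGrid <- c(checkCount(patchGrid[1], "patchGrid[1]"),
                 checkCount(patchGrid[2], "patchGrid[2]"))
  spec <- list(
    nImages = nImages, nClasses = nClasses, patchGrid = patchGrid,
    featureDim = checkCount(featureDim, "featureDim"),
    nComponents = checkCount(nComponents, "nComponents"),
    classSeparation = checkNumber(classSeparation, "classSeparation", min = 0),
    noiseSd = checkNumber(noiseSd, "noiseSd", min = 0),
    imageSize = checkCount(imageSize, "imageSize", 1L),
    seed = checkCount(seed, "seed", min = -.Machine$integer.max))
  class(spec) <- "syntheticSpec"
  spec
}

## Balanced 0-based labels, every class present (nImages >= nClasses).
syntheticLabels <- function(spec)
  rep(seq_len(spec$nClasses) - 1L, length.out = spec$nImages)

## Shared mixture geometry: component base means (shared across classes) and
## one unit offset direction per class. Drawing happens inside the caller's
## seeded RNG scope.
mixtureGeometry <- function(spec) {
  G <- matrix(rnorm(spec$nComponents * spec$featureDim),
              spec$nComponents, spec$featureDim)
  U <- matrix(rnorm(spec$nClasses * spec$featureDim),
              spec$nClasses, spec$featureDim)
  U <- U / sqrt(rowSums(U^2))
  list(G = G, U = U)
}

#' Generate a synthetic patch-feature dataset
#'
#' Draws one [PatchFeatureMatrix-class] per image. Patch rows of an image with
#' class `c` are sampled as `G[j, ] + classSeparation * U[c, ] + noise`, where
#' the component means `G` are shared across classes, `U[c, ]` is a unit
#' direction unique to class `c`, component `j` is resampled per patch, and
#' the noise is isotropic Gaussian with `noiseSd`. With `classSeparation = 0`
#' the per-class distributions are identical; with `noiseSd = 0` and a single
#' component all patches of a class equal the class mean exactly.
#'
#' @param spec a [syntheticSpec()].
#' @return List with `features` (list of [PatchFeatureMatrix-class]),
#'   `labels` (0-based integer vector) and `spec`.
#' @export
generateFeatureDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  labels <- syntheticLabels(spec)
  nPatches <- prod(spec$patchGrid)
  withSeed(spec$seed, {
    geo <- mixtureGeometry(spec)
    feats <- lapply(seq_len(spec$nImages), function(i) {
      cls <- labels[i] + 1L
      comp <- sample.int(spec$nComponents, nPatches, replace = TRUE)
      mu <- geo$G[comp, , drop = FALSE] +
        matrix(spec$classSeparation * geo$U[cls, ], nPatches,
               spec$featureDim, byrow = TRUE)
      X <- mu
      if (spec$noiseSd > 0)
        X <- X + matrix(rnorm(nPatches * spec$featureDim, sd = spec$noiseSd),
                        nPatches, spec$featureDim)
      PatchFeatureMatrix(X, spec$patchGrid,
                         imageId = sprintf("synth_%04d", i),
                         extractorName = "synthetic")
    })
    list(features = feats, labels = labels, spec = spec)
  })
}

#' Generate a synthetic labeled image dataset
#'
#' Produces RGB [ImageRecord-class]s with class-dependent block textures: an
#' 8 x 8 block pattern shared by all classes is shifted by a class-specific
#' block pattern scaled by `classSeparation` (0.05 pixel units per separation
#' unit), pixel noise with sd `0.05 * noiseSd` is added, and values are
#' clipped to `[0, 1]`. Identical specs give pixel-identical images.
#'
#' @param spec a [syntheticSpec()] with `imageSize >= 32`.
#' @return List with `images` (list of [ImageRecord-class]), `labels` and
#'   `spec`.
#' @export
generateImageDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  if (spec$imageSize < 32L)
    stop("imageSize must be >= 32 for image-mode generation", call. = FALSE)
  labels <- syntheticLabels(spec)
  s <- spec$imageSize
  blockIdx <- pmin(floor((seq_len(s) - 1L) / (s / 8)) + 1L, 8L)
  withSeed(spec$seed, {
    base <- array(runif(8 * 8 * 3, 0.3, 0.7), c(8, 8, 3))
    classPat <- lapply(seq_len(spec$nClasses),
                       function(c) array(runif(8 * 8 * 3, -1, 1), c(8, 8, 3)))
    images <- lapply(seq_len(spec$nImages), function(i) {
      cls <- labels[i] + 1L
      blocks <- base + 0.05 * spec$classSeparation * classPat[[cls]]
      px <- blocks[blockIdx, blockIdx, , drop = FALSE]
      if (spec$noiseSd > 0)
        px <- px + array(rnorm(s * s * 3, sd = 0.05 * spec$noiseSd),
                         c(s, s, 3))
      px <- pmin(pmax(px, 0), 1)
      ImageRecord(px, imageId = sprintf("synth_%04d", i),
                  label = labels[i])
    })
    list(images = images, labels = labels, spec = spec)
  })
}

#' Write / read a feature dataset as CSV files plus a manifest
#'
#' Each image's patch-feature matrix is written as one CSV file and a
#' `manifest.csv` records `image_id, label, path, rows, cols, dim, extractor`.
#'
#' @param dataset the output of [generateFeatureDataset()] (or a compatible
#'   list with `features` and `labels`).
#' @param dir output directory, created if needed.
#' @return `writeFeatureDataset` returns the manifest data frame invisibly;
#'   `readFeatureDataset` returns a list with `features` and `labels`.
#' @export
writeFeatureDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(dataset$features, function(f)
    file.path(dir, paste0(imageId(f), ".csv")), "")
  for (i in seq_along(dataset$features))
    write.csv(features(dataset$features[[i]]), paths[i], row.names = FALSE)
  manifest <- data.frame(
    image_id = vapply(dataset$features, imageId, ""),
    label = dataset$labels,
    path = basename(paths),
    rows = vapply(dataset$features, function(f) featureGrid(f)[1], 1L),
    cols = vapply(dataset$features, function(f) featureGrid(f)[2], 1L),
    dim = vapply(dataset$features, function(f) ncol(features(f)), 1L),
    extractor = vapply(dataset$features, extractorName, ""))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname writeFeatureDataset
#' @export
readFeatureDataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  feats <- lapply(seq_len(nrow(manifest)), function(i) {
    X <- as.matrix(read.csv(file.path(dir, manifest$path[i])))
    dimnames(X) <- NULL
    PatchFeatureMatrix(X, c(manifest$rows[i], manifest$cols[i]),
                       imageId = manifest$image_id[i],
                       extractorName = manifest$extractor[i])
  })
  list(features = feats, labels = as.integer(manifest$label))
}

#' Write an image dataset as a class-subfolder tree of PNG files
#'
#' Creates `dir/class_<label>/<image_id>.png` for every image, the layout
#' consumed by [readImageFolder()].
#'
#' @param dataset output of [generateImageDataset()].
#' @param dir output directory.
#' @return Invisibly, the written file paths.
#' @export
writeImageDataset <- function(dataset, dir) {
  paths <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    img <- dataset$images[[i]]
    sub <- file.path(dir, paste0("class_", dataset$labels[i]))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, paste0(imageId(img), ".png"))
    EBImage::writeImage(EBImage::Image(aperm(pixels(img), c(2, 1, 3)),
                                       colormode = "Color"), paths[i])
  }
  invisible(paths)
}
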