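#' @import methods
#' @importFrom stats kmeans qt rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib HistoGraphFusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Central data containers
## ---------------------------------------------------------------------------

#' ImageRecord: one labeled RGB image
#'
#' Holds one RGB image as an `H x W x 3` numeric array together with an
#' identifier and an optional class label (0-based integer, `NA` when
#' unlabeled). Raw images live in `[0, 1]`; images that have passed through
#' [preprocessImage()] are channel-standardized and may take any finite value.
#'
#' @slot pixels numeric array, `H x W x 3`, all entries finite.
#' @slot imageId character scalar identifier.
#' @slot label integer scalar class index (0-based) or `NA`.
#'
#' @seealso [ImageRecord()], [generateImageDataset()], [preprocessImage()]
#' @export
setClass("ImageRecord",
  representation(pixels = "array", imageId = "character", label = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 1L || d[2] < 1L)
      return("image height and width must be >= 1")
    if (!all(is.finite(object@pixels)))
      return("pixels must be finite")
    if (length(object@imageId) != 1L)
      return("imageId must be a single string")
    if (length(object@label) != 1L)
      return("label must be a single integer (NA allowed)")
    TRUE
  }
)

#' Construct an ImageRecord
#'
#' @param pixels `H x W x 3` numeric array.
#' @param imageId character identifier.
#' @param label 0-based integer class label, or `NA`.
#' @return An [ImageRecord-class] object.
#' @examples
#' img <- ImageRecord(array(0.5, c(8, 8, 3)), "img1", label = 0L)
#' dim(pixels(img))
#' @export
ImageRecord <- function(pixels, imageId = "image", label = NA_integer_) {
  new("ImageRecord", pixels = pixels, imageId = as.character(imageId),
      label = as.integer(label))
}

#' PatchFeatureMatrix: per-image patch embeddings
#'
#' The `n_patches x dim` matrix of local feature vectors for one image,
#' flattened row-major over the spatial grid (top-left patch first). This is
#' the object k-means clustering consumes during graph construction; for a
#' transformer backbone at 224 px input it is the spatial token grid, e.g.
#' `196 x 768` for a 16 px patch size.
#'
#' @slot features numeric matrix, `n_patches x dim`, finite.
#' @slot grid integer length-2 `(rows, cols)` with `rows * cols == n_patches`.
#' @slot imageId character identifier of the source image.
#' @slot extractorName character name of the extractor that produced it.
#'
#' @seealso [PatchFeatureMatrix()], [extractFeatures()], [buildGraph()]
#' @export
setClass("PatchFeatureMatrix",
  representation(features = "matrix", grid = "integer",
                 imageId = "character", extractorName = "character"),
  validity = function(object) {
    if (length(object@grid) != 2L || any(object@grid < 1L))
      return("grid must be two positive integers (rows, cols)")
    if (nrow(object@features) != prod(object@grid))
      return("nrow(features) must equal rows * cols of the grid")
    if (!all(is.finite(object@features)))
      return("features must contain only finite values")
    TRUE
  }
)

#' Construct a PatchFeatureMatrix
#'
#' @param features `n_patches x dim` numeric matrix (row-major grid order).
#' @param grid integer `(rows, cols)`; `rows * cols` must equal
#'   `nrow(features)`.
#' @param imageId character identifier.
#' @param extractorName name of the producing extractor.
#' @return A [PatchFeatureMatrix-class] object.
#' @examples
#' pfm <- PatchFeatureMatrix(matrix(rnorm(4 * 8), 4, 8), c(2L, 2L), "img1")
#' featureGrid(pfm)
#' @export
PatchFeatureMatrix <- function(features, grid, imageId = "image",
                               extractorName = "unknown") {
  new("PatchFeatureMatrix", features = features, grid = as.integer(grid),
      imageId = as.character(imageId), extractorName = as.character(extractorName))
}

#' ImageGraph: centroid nodes plus thresholded cosine edges
#'
#' One image condensed to a graph: node features are the k-means centroids of
#' the image's patch embeddings and the directed edge list connects centroid
#' pairs whose cosine similarity exceeds the build threshold. Edges are stored
#' without self-loops and are symmetric: `(i, j)` is present iff `(j, i)` is.
#' Node indices in the edge list are 1-based.
#'
#' @slot nodeFeatures numeric matrix, `k' x dim` cluster centroids.
#' @slot edges integer matrix with two columns `(src, dst)`; may have 0 rows.
#' @slot imageId character identifier.
#' @slot label integer class index (0-based) or `NA`.
#'
#' @seealso [buildGraph()], [trainGAT()]
#' @export
setClass("ImageGraph",
  representation(nodeFeatures = "matrix", edges = "matrix",
                 imageId = "character", label = "integer"),
  validity = function(object) {
    k <- nrow(object@nodeFeatures)
    if (k < 1L) return("graph must have at least one node")
    if (!all(is.finite(object@nodeFeatures)))
      return("node features must be finite")
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns (src, dst)")
    if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > k)) return("edge indices out of range")
      if (any(e[, 1L] == e[, 2L])) return("self-loops are not stored")
      key <- (e[, 1L] - 1) * k + (e[, 2L] - 1)
      rev <- (e[, 2L] - 1) * k + (e[, 1L] - 1)
      if (!all(rev %in% key)) return("edge list must be symmetric")
    }
    TRUE
  }
)

#' Construct an ImageGraph
#'
#' @param nodeFeatures `k' x dim` numeric centroid matrix.
#' @param edges two-column integer matrix of directed edges (1-based,
#'   symmetric, no self-loops). Defaults to no edges.
#' @param imageId character identifier.
#' @param label 0-based integer class label or `NA`.
#' @return An [ImageGraph-class] object.
#' @export
ImageGraph <- function(nodeFeatures, edges = matrix(integer(0), 0, 2),
                       imageId = "image", label = NA_integer_) {
  storage.mode(edges) <- "integer"
  dimnames(edges) <- list(NULL, c("src", "dst"))
  dimnames(nodeFeatures) <- NULL
  new("ImageGraph", nodeFeatures = nodeFeatures, edges = edges,
      imageId = as.character(imageId), label = as.integer(label))
}

#' ProbabilityMatrix: per-sample class probabilities
#'
#' An `n_samples x n_classes` matrix of class probabilities; every row is
#' nonnegative and sums to one (within 1e-6). This is the currency of
#' prediction fusion: the weighted-average rule combines two of these row by
#' row.
#'
#' @slot probs numeric matrix of probabilities.
#' @slot sampleIds character vector of row identifiers.
#'
#' @seealso [predictProba()], [weightedAverage()]
#' @export
setClass("ProbabilityMatrix",
  representation(probs = "matrix", sampleIds = "character"),
  validity = function(object) {
    p <- object@probs
    if (!all(is.finite(p)) || any(p < 0))
      return("probabilities must be finite and nonnegative")
    if (nrow(p) > 0L && any(abs(rowSums(p) - 1) > 1e-6))
      return("every row must sum to 1 within 1e-6")
    if (length(object@sampleIds) != nrow(p))
      return("sampleIds length must match the number of rows")
    TRUE
  }
)

#' Construct a ProbabilityMatrix
#'
#' @param probs `n_samples x n_classes` numeric matrix; rows must sum to 1.
#' @param sampleIds character row identifiers (defaults to `"s1"`, `"s2"`...).
#' @return A [ProbabilityMatrix-class] object.
#' @export
ProbabilityMatrix <- function(probs, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(probs)))
  new("ProbabilityMatrix", probs = probs, sampleIds = as.character(sampleIds))
}

#' CVSummary: cross-validated metric with Student-t confidence interval
#'
#' Per-fold values of one metric for one model, with their mean, sample
#' standard deviation (divisor `n - 1`) and the two-sided Student-t
#' confidence interval `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)`.
#'
#' @slot metric character metric name.
#' @slot model character model name.
#' @slot perFold numeric per-fold metric values.
#' @slot mean,sd,ciLow,ciHigh,level numeric scalars.
#'
#' @seealso [cvSummary()], [tConfidenceInterval()]
#' @export
setClass("CVSummary",
  representation(metric = "character", model = "character",
                 perFold = "numeric", mean = "numeric", sd = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", level = "numeric"),
  validity = function(object) {
    if (length(object@perFold) < 2L) return("need at least two fold values")
    if (!(object@ciLow <= object@mean && object@mean <= object@ciHigh))
      return("interval must contain the mean")
    if (abs((object@mean - object@ciLow) - (object@ciHigh - object@mean)) > 1e-8)
      return("interval must be symmetric about the mean")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Accessor generics
## ---------------------------------------------------------------------------

#' @rdname ImageRecord-class
#' @param object an object of the documented class.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname ImageRecord-class
#' @export
setMethod("pixels", "ImageRecord", function(object) object@pixels)

#' @rdname ImageRecord-class
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname ImageRecord-class
#' @export
setMethod("imageId", "ImageRecord", function(object) object@imageId)
#' @rdname PatchFeatureMatrix-class
#' @export
setMethod("imageId", "PatchFeatureMatrix", function(object) object@imageId)
#' @rdname ImageGraph-class
#' @export
setMethod("imageId", "ImageGraph", function(object) object@imageId)

#' @rdname ImageRecord-class
#' @export
setGeneric("imageLabel", function(object) standardGeneric("imageLabel"))
#' @rdname ImageRecord-class
#' @export
setMethod("imageLabel", "ImageRecord", function(object) object@label)
#' @rdname ImageGraph-class
#' @export
setMethod("imageLabel", "ImageGraph", function(object) object@label)

#' @rdname PatchFeatureMatrix-class
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname PatchFeatureMatrix-class
#' @export
setMethod("features", "PatchFeatureMatrix", function(object) object@features)

#' @rdname PatchFeatureMatrix-class
#' @export
setGeneric("featureGrid", function(object) standardGeneric("featureGrid"))
#' @rdname PatchFeatureMatrix-class
#' @export
setMethod("featureGrid", "PatchFeatureMatrix", function(object) object@grid)

#' @rdname PatchFeatureMatrix-class
#' @export
setGeneric("extractorName", function(object) standardGeneric("extractorName"))
#' @rdname PatchFeatureMatrix-class
#' @export
setMethod("extractorName", "PatchFeatureMatrix",
          function(object) object@extractorName)

#' @rdname ImageGraph-class
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
#' @rdname ImageGraph-class
#' @export
setMethod("nodeFeatures", "ImageGraph", function(object) object@nodeFeatures)

#' @rdname ImageGraph-class
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname ImageGraph-class
#' @export
setMethod("graphEdges", "ImageGraph", function(object) object@edges)

#' @rdname ProbabilityMatrix-class
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))
#' @rdname ProbabilityMatrix-class
#' @export
setMethod("probs", "ProbabilityMatrix", function(object) object@probs)

#' @rdname ProbabilityMatrix-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname ProbabilityMatrix-class
#' @export
setMethod("sampleIds", "ProbabilityMatrix", function(object) object@sampleIds)

#' @rdname CVSummary-class
#' @export
setGeneric("perFoldValues", function(object) standardGeneric("perFoldValues"))
#' @rdname CVSummary-class
#' @export
setMethod("perFoldValues", "CVSummary", function(object) object@perFold)

#' @rdname CVSummary-class
#' @export
setGeneric("confint2", function(object) standardGeneric("confint2"))
#' @rdname CVSummary-class
#' @export
setMethod("confint2", "CVSummary",
          function(object) c(low = object@ciLow, high = object@ciHigh))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ImageRecord", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageRecord '%s': %d x %d x 3, label = %s\n",
              object@imageId, d[1], d[2],
              ifelse(is.na(object@label), "NA", object@label)))
})

setMethod("show", "PatchFeatureMatrix", function(object) {
  cat(sprintf("PatchFeatureMatrix '%s' [%s]: %d patches (%d x %d grid) x %d features\n",
              object@imageId, object@extractorName, nrow(object@features),
              object@grid[1], object@grid[2], ncol(object@features)))
})

setMethod("show", "ImageGraph", function(object) {
  cat(sprintf("ImageGraph '%s': %d nodes x %d features, %d directed edges, label = %s\n",
              object@imageId, nrow(object@nodeFeatures),
              ncol(object@nodeFeatures), nrow(object@edges),
              ifelse(is.na(object@label), "NA", object@label)))
})

setMethod("show", "ProbabilityMatrix", function(object) {
  cat(sprintf("ProbabilityMatrix: %d samples x %d classes\n",
              nrow(object@probs), ncol(object@probs)))
  if (nrow(object@probs) > 0)
    print(utils::head(object@probs, 3L))
})

setMethod("show", "CVSummary", function(object) {
  cat(sprintf("%s / %s: %.2f (+/- %.2f), %d folds, %g%% CI [%.2f, %.2f]\n",
              object@model, object@metric, object@mean, object@sd,
              length(object@perFold), 100 * object@level,
              object@ciLow, object@ciHigh))
})
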