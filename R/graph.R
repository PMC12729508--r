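#' Graph-construction configuration
#'
#' Parameters controlling how one patch-feature matrix becomes one graph:
#' the number of k-means clusters whose centroids form the nodes (default
#' 100, keeping the model lightweight) and the cosine-similarity threshold
#' above which bidirectional edges are added (default 0.6, the empirically
#' chosen operating point; both are the ablation axes of the method).
#'
#' @param nClusters requested number of k-means clusters (capped at the
#'   number of patches).
#' @param similarityThreshold cosine threshold in `[-1, 1]`; an edge pair is
#'   added iff similarity strictly exceeds it.
#' @param kmeansSeed seed for the k-means++ initialisation (fixed for
#'   reproducibility).
#' @param kmeansMaxIter maximum Lloyd iterations.
#' @param kmeansRestarts independent seeded restarts; the fit with the lowest
#'   total within-cluster sum of squares wins.
#' @return A validated `graphBuildConfig` list.
#' @export
graphBuildConfig <- function(nClusters = 100L, similarityThreshold = 0.6,
                             kmeansSeed = 42L, kmeansMaxIter = 300L,
                             kmeansRestarts = 1L) {
  structure(list(
    nClusters = checkCount(nClusters, "nClusters"),
    similarityThreshold = checkNumber(similarityThreshold,
                                      "similarityThreshold", -1, 1),
    kmeansSeed = checkCount(kmeansSeed, "kmeansSeed",
                            min = -.Machine$integer.max),
    kmeansMaxIter = checkCount(kmeansMaxIter, "kmeansMaxIter"),
    kmeansRestarts = checkCount(kmeansRestarts, "kmeansRestarts")),
    class = "graphBuildConfig")
}

## k-means++ seeding: first center uniform, subsequent centers sampled with
## probability proportional to squared distance from the nearest chosen
## center. Returns distinct row indices (fewer than k if the data admit
## fewer distinct points). Uses the current RNG scope.
kmeansppInit <- function(X, k) {
  n <- nrow(X)
  sq <- rowSums(X * X)
  distTo <- function(i)
    pmax(sq - 2 * drop(X %*% X[i, ]) + sq[i], 0)
  first <- sample.int(n, 1L)
  idx <- first
  d2 <- distTo(first)
  while (length(idx) < k) {
    tot <- sum(d2)
    if (tot <= 0) break    # every remaining point duplicates a center
    nxt <- sample.int(n, 1L, prob = d2 / tot)
    if (d2[nxt] <= 0) {
      cand <- which(d2 > 0)
      if (length(cand) == 0L) break
      nxt <- cand[which.max(d2[cand])]
    }
    idx <- c(idx, nxt)
    d2 <- pmin(d2, distTo(nxt))
  }
  idx
}

## Order cluster ids by the index of the first patch assigned to each, so
## centroid order is deterministic and tied to the row-major patch order.
orderByFirstAssignment <- function(assign, nCenters) {
  first <- vapply(seq_len(nCenters), function(c) {
    w <- which(assign == c)
    if (length(w) == 0L) Inf else as.numeric(w[1L])
  }, 0)
  order(first)
}

#' Cluster an image's patches into centroid nodes
#'
#' Partitions the `n_patches x dim` feature matrix with k-means (Lloyd,
#' k-means++ seeded, fixed seed) and returns the cluster centroids that will
#' serve as graph nodes. The effective number of clusters is
#' `min(nClusters, n_patches)`; clusters left empty are dropped, so the
#' result may have fewer rows. Centroids are ordered by the index of the
#' first patch assigned to each cluster.
#'
#' @param x a [PatchFeatureMatrix-class] or a plain numeric matrix.
#' @param config a [graphBuildConfig()].
#' @return A `k' x dim` centroid matrix.
#' @examples
#' cfg <- graphBuildConfig(nClusters = 2)
#' pts <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 10), 3))
#' dim(clusterPatches(pts, cfg))
#' @export
clusterPatches <- function(x, config = graphBuildConfig()) {
  X <- if (is(x, "PatchFeatureMatrix")) features(x) else x
  if (!is.matrix(X) || nrow(X) < 1L)
    stop("need at least one patch", call. = FALSE)
  if (!all(is.finite(X)))
    stop("patch features must be finite", call. = FALSE)
  k <- min(config$nClusters, nrow(X))
  if (k == nrow(X))
    return(X)
  best <- NULL
  for (r in seq_len(config$kmeansRestarts)) {
    fit <- withSeed(config$kmeansSeed + r - 1L, {
      idx <- kmeansppInit(X, k)
      if (length(idx) < k) {
        ## fewer distinct points than clusters: the distinct points are the
        ## exact optimum
        assign <- apply(X, 1L, function(row)
          which.min(colSums((t(X[idx, , drop = FALSE]) - row)^2)))
        list(centers = X[idx, , drop = FALSE], cluster = assign,
             tot.withinss = 0)
      } else {
        suppressWarnings(stats::kmeans(X, centers = X[idx, , drop = FALSE],
                                       iter.max = config$kmeansMaxIter,
                                       algorithm = "Lloyd"))
      }
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  keep <- which(tabulate(best$cluster, nrow(best$centers)) > 0L)
  centers <- best$centers[keep, , drop = FALSE]
  assign <- match(best$cluster, keep)
  ord <- orderByFirstAssignment(assign, nrow(centers))
  centers <- centers[ord, , drop = FALSE]
  dimnames(centers) <- NULL
  centers
}

#' Cosine similarity matrix over centroids
#'
#' `S[i, j] = <c_i, c_j> / (||c_i|| ||c_j||)`. Rows with zero norm have
#' similarity 0 against everything (including themselves), so degenerate
#' centroids never create edges.
#'
#' @param centroids `k' x dim` numeric matrix.
#' @return Symmetric `k' x k'` similarity matrix with unit diagonal for
#'   nonzero rows.
#' @examples
#' cosineSimilarity(rbind(c(1, 1), c(1, 0)))[1, 2]   # 1/sqrt(2)
#' @export
cosineSimilarity <- function(centroids) {
  stopifnot(is.matrix(centroids), nrow(centroids) >= 1L)
  nrm <- sqrt(rowSums(centroids^2))
  scaled <- centroids
  nz <- nrm > 0
  scaled[nz, ] <- centroids[nz, , drop = FALSE] / nrm[nz]
  scaled[!nz, ] <- 0
  S <- tcrossprod(scaled)
  S <- (S + t(S)) / 2                 # enforce exact symmetry
  pmin(pmax(S, -1), 1)
}

#' Thresholded edge list from a similarity matrix
#'
#' Returns every ordered pair `(i, j)`, `i != j`, with `S[i, j]` strictly
#' greater than the threshold. Because `S` is symmetric, edges come in
#' bidirectional pairs; nodes whose similarities never exceed the threshold
#' simply remain isolated.
#'
#' @param S symmetric similarity matrix.
#' @param threshold edge threshold (strict inequality).
#' @return Two-column integer matrix of directed edges (1-based), possibly
#'   with zero rows.
#' @export
buildEdges <- function(S, threshold = 0.6) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  hit <- which(S > threshold & !diag(TRUE, nrow(S)), arr.ind = TRUE)
  e <- cbind(src = as.integer(hit[, 1L]), dst = as.integer(hit[, 2L]))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Build the graph of one image
#'
#' Composition of [clusterPatches()], [cosineSimilarity()] and
#' [buildEdges()]: patch embeddings are condensed to centroid nodes and
#' bidirectional edges connect centroid pairs whose cosine similarity
#' exceeds the threshold.
#'
#' @param x a [PatchFeatureMatrix-class] (or plain matrix).
#' @param config a [graphBuildConfig()].
#' @param label optional 0-based class label carried onto the graph; when
#'   `x` is a `PatchFeatureMatrix` its image id is carried over too.
#' @return An [ImageGraph-class].
#' @export
buildGraph <- function(x, config = graphBuildConfig(), label = NA_integer_) {
  centers <- clusterPatches(x, config)
  S <- cosineSimilarity(centers)
  e <- buildEdges(S, config$similarityThreshold)
  ImageGraph(centers, e,
             imageId = if (is(x, "PatchFeatureMatrix")) imageId(x) else "image",
             label = as.integer(label))
}

#' Build graphs for a list of feature matrices
#'
#' @param featureList list of [PatchFeatureMatrix-class].
#' @param config a [graphBuildConfig()].
#' @param labels optional 0-based integer labels, recycled onto the graphs.
#' @return List of [ImageGraph-class].
#' @export
buildGraphs <- function(featureList, config = graphBuildConfig(),
                        labels = NULL) {
  if (is.null(labels)) labels <- rep(NA_integer_, length(featureList))
  stopifnot(length(labels) == length(featureList))
  lapply(seq_along(featureList), function(i)
    buildGraph(featureList[[i]], config, labels[i]))
}

#' Write / read one image graph as plain-text files
#'
#' Node features go to `<stem>_nodes.csv`; the directed edge list goes to
#' `<stem>_edges.csv` with 0-based `src, dst` columns.
#'
#' @param graph an [ImageGraph-class].
#' @param stem file path stem (no extension).
#' @return `writeGraph` invisibly returns the two paths; `readGraph` returns
#'   the reconstructed [ImageGraph-class].
#' @export
writeGraph <- function(graph, stem) {
  nodesPath <- paste0(stem, "_nodes.csv")
  edgesPath <- paste0(stem, "_edges.csv")
  write.csv(nodeFeatures(graph), nodesPath, row.names = FALSE)
  e <- graphEdges(graph)
  write.csv(data.frame(src = e[, 1L] - 1L, dst = e[, 2L] - 1L),
            edgesPath, row.names = FALSE)
  invisible(c(nodes = nodesPath, edges = edgesPath))
}

#' @rdname writeGraph
#' @param imageId,label metadata restored onto the graph read back.
#' @export
readGraph <- function(stem, imageId = "image", label = NA_integer_) {
  nodes <- as.matrix(read.csv(paste0(stem, "_nodes.csv")))
  dimnames(nodes) <- NULL
  e <- read.csv(paste0(stem, "_edges.csv"))
  ImageGraph(nodes, cbind(as.integer(e$src) + 1L, as.integer(e$dst) + 1L),
             imageId = imageId, label = label)
}
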