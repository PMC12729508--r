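# Shared fixtures and independent oracles. Everything here is deliberately
# written without reusing the package's own computational paths, so tests
# compare two independent routes.

makeRandomGraph <- function(n, d, label = 0L, threshold = 0, seed = 1L,
                            id = paste0("g", seed)) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  S <- cosineSimilarity(X)
  ImageGraph(X, buildEdges(S, threshold), imageId = id,
             label = as.integer(label))
}

# Reference graph-attention forward pass: plain R, loops over nodes, one
# graph at a time. Independent of the compiled implementation.
refAttentionLayer <- function(X, edges, W, As, Ad, b, H, D, slope,
                              selfLoops) {
  n <- nrow(X)
  e <- edges
  if (selfLoops) e <- rbind(e, cbind(seq_len(n), seq_len(n)))
  Z <- X %*% W
  out <- matrix(0, n, H * D)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * D + 1):(h * D)
    Zh <- Z[, cols, drop = FALSE]
    ss <- drop(Zh %*% As[, h])
    sdd <- drop(Zh %*% Ad[, h])
    for (i in seq_len(n)) {
      inc <- which(e[, 2] == i)
      if (length(inc) == 0) next
      sc <- ss[e[inc, 1]] + sdd[i]
      sc <- ifelse(sc > 0, sc, slope * sc)
      a <- exp(sc - max(sc))
      a <- a / sum(a)
      out[i, cols] <- colSums(a * Zh[e[inc, 1], , drop = FALSE])
    }
  }
  sweep(out, 2, b[, 1], "+")
}

refGatLogits <- function(params, graph, cfg) {
  X <- nodeFeatures(graph)
  e <- graphEdges(graph)
  h1 <- pmax(refAttentionLayer(X, e, params$W1, params$a1_src,
                               params$a1_dst, params$b1, cfg$layer1Heads,
                               cfg$layer1PerHead, cfg$attentionSlope,
                               cfg$addSelfLoops), 0)
  h2 <- pmax(refAttentionLayer(h1, e, params$W2, params$a2_src,
                               params$a2_dst, params$b2, cfg$layer2Heads,
                               cfg$layer2PerHead, cfg$attentionSlope,
                               cfg$addSelfLoops), 0)
  pooled <- colMeans(h2)
  drop(pooled %*% params$W_out + params$b_out[, 1])
}

# Brute-force optimal 2-means: enumerate every 2-partition and minimise the
# within-cluster sum of squares.
bruteForceTwoMeans <- function(X) {
  n <- nrow(X)
  best <- NULL
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    c1 <- colMeans(X[grp, , drop = FALSE])
    c2 <- colMeans(X[!grp, , drop = FALSE])
    wss <- sum(sweep(X[grp, , drop = FALSE], 2, c1)^2) +
      sum(sweep(X[!grp, , drop = FALSE], 2, c2)^2)
    if (is.null(best) || wss < best$wss)
      best <- list(wss = wss, centers = rbind(c1, c2))
  }
  best
}

# Independent one-vs-rest counting of precision/recall/F1 via logical sums.
oraclePerClassF1 <- function(yt, yp, cls) {
  tp <- sum(yt == cls & yp == cls)
  fp <- sum(yt != cls & yp == cls)
  fn <- sum(yt == cls & yp != cls)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

oracleMacroF1 <- function(yt, yp, C)
  mean(vapply(0:(C - 1), function(c) oraclePerClassF1(yt, yp, c), 0))

oracleMacroRecall <- function(yt, yp, C)
  mean(vapply(0:(C - 1), function(c) {
    sum(yt == c & yp == c) / sum(yt == c)
  }, 0))

randomProbMatrix <- function(n, C, seed) {
  set.seed(seed)
  P <- matrix(rexp(n * C), n, C)
  P / rowSums(P)
}

smallTrainConfig <- function(epochs = 60L, lr = 1e-3, seed = 1L,
                             batchSize = 16L)
  trainConfig(learningRate = lr, epochs = epochs, batchSize = batchSize,
              seed = seed)
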