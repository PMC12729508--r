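## Internal helpers shared across modules.

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so package functions never disturb user randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a logit matrix.
#'
#' @param logits numeric matrix (`n x C`) or vector.
#' @return Matrix of the same shape whose rows are positive and sum to 1.
#' @examples
#' softmaxRows(matrix(c(log(3), 0), 1))   # (0.75, 0.25)
#' @export
softmaxRows <- function(logits) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1L)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

checkNumber <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  as.numeric(x)
}

## Deterministic md5 hash of a canonical character representation of a
## configuration list. Function-valued fields are replaced by their name
## attribute (or "<function>") so the hash does not depend on environments.
configHash <- function(cfg) {
  canon <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.list(x)) {
      nm <- names(x)
      if (is.null(nm)) nm <- rep("", length(x))
      ord <- order(nm)
      return(paste0("{", paste0(nm[ord], ":",
                                vapply(x[ord], canon, ""), collapse = ","), "}"))
    }
    paste(format(x, digits = 17), collapse = ",")
  }
  txt <- canon(cfg)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

## ---------------------------------------------------------------------------
## Minimal Adam-trained multilayer perceptron (softmax + cross-entropy).
## Used for the baseline linear head, frozen-backbone fine-tuning and the
## stacking meta-learners. `hidden` is a vector of hidden widths (possibly
## empty, in which case the model is multinomial logistic regression).
## ---------------------------------------------------------------------------

glorotMatrix <- function(fanIn, fanOut) {
  s <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -s, s), fanIn, fanOut)
}

mlpInit <- function(inDim, hidden, nClasses, seed) {
  withSeed(seed, {
    dims <- c(inDim, hidden, nClasses)
    lapply(seq_len(length(dims) - 1L), function(l)
      list(W = glorotMatrix(dims[l], dims[l + 1L]),
           b = numeric(dims[l + 1L])))
  })
}

mlpForward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(layers)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < length(layers)) pmax(Z, 0) else Z
  }
  acts
}

## One Adam step on a parameter list given same-shaped gradients.
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + eps)
  }
  list(params = params, state = state)
}

flattenLayers <- function(layers)
  unlist(lapply(layers, function(l) list(l$W, l$b)), recursive = FALSE)

rebuildLayers <- function(flat) {
  n <- length(flat) / 2L
  lapply(seq_len(n), function(l) list(W = flat[[2L * l - 1L]],
                                      b = flat[[2L * l]]))
}

mlpTrain <- function(X, y, nClasses, hidden = integer(0), lr = 1e-4,
                     epochs = 300L, batchSize = 32L, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  layers <- mlpInit(ncol(X), hidden, nClasses, seed)
  flat <- flattenLayers(layers)
  state <- list(t = 0L,
                m = lapply(flat, function(p) p * 0),
                v = lapply(flat, function(p) p * 0))
  n <- nrow(X)
  lossHistory <- numeric(epochs)
  withSeed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      epLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batchSize - 1L, n)]
        layers <- rebuildLayers(flat)
        acts <- mlpForward(layers, X[idx, , drop = FALSE])
        logits <- acts[[length(acts)]]
        P <- softmaxRows(logits)
        b <- length(idx)
        epLoss <- epLoss - sum(log(pmax(P[cbind(seq_len(b), y[idx] + 1L)],
                                        1e-12)))
        dZ <- P
        dZ[cbind(seq_len(b), y[idx] + 1L)] <-
          dZ[cbind(seq_len(b), y[idx] + 1L)] - 1
        dZ <- dZ / b
        grads <- vector("list", length(flat))
        for (l in rev(seq_along(layers))) {
          A <- acts[[l]]
          grads[[2L * l - 1L]] <- crossprod(A, dZ)
          grads[[2L * l]] <- colSums(dZ)
          if (l > 1L) {
            dA <- tcrossprod(dZ, layers[[l]]$W)
            dZ <- dA * (acts[[l]] > 0)
          }
        }
        upd <- adamStep(flat, grads, state, lr)
        flat <- upd$params
        state <- upd$state
      }
      lossHistory[ep] <- epLoss / n
    }
  })
  structure(list(layers = rebuildLayers(flat), nClasses = nClasses,
                 lossHistory = lossHistory),
            class = "hgfMlp")
}

mlpPredictProba <- function(model, X) {
  acts <- mlpForward(model$layers, X)
  softmaxRows(acts[[length(acts)]])
}
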