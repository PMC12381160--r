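# Small neural-network toolkit: nested-list parameters, tree arithmetic,
# Adam, and forward/backward primitives (linear, layer norm, softmax
# attention) used by the dual-stream model and the autoencoder. Everything
# is plain double-precision matrix algebra; gradients are analytic and are
# cross-checked against finite differences in the test suite.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

addRows <- function(m, b) sweep(m, 2, b, "+")

# elementwise operations over nested parameter lists
mapTree <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(x) mapTree(f, x))
           else lapply(seq_along(a), function(i) mapTree(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}
zeroTree <- function(p) mapTree(function(x) x * 0, p)
addTree <- function(a, b) mapTree(`+`, a, b)
scaleTree <- function(a, s) mapTree(function(x) x * s, a)

flattenTree <- function(p) unlist(p, use.names = FALSE)

unflattenTree <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) {
      out <- lapply(s, walk); names(out) <- names(s); out
    } else {
      n <- length(s)
      v <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(s))) dim(v) <- dim(s)
      v
    }
  }
  walk(skeleton)
}

adamInit <- function(params) {
  list(m = zeroTree(params), v = zeroTree(params), t = 0L)
}

adamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapTree(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- mapTree(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- mapTree(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  list(params = mapTree(`-`, params, step), state = state)
}

glorot <- function(a, b) matrix(stats::runif(a * b, -1, 1) * sqrt(6 / (a + b)), a, b)

# layer norm over the feature dimension, per row (population variance)
lnForward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = addRows(sweep(xhat, 2, g, "*"), b), xhat = xhat, inv = inv)
}

lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmaxRows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

softmaxRowsBackward <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

dropoutForward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  keep <- 1 - rate
  mask <- matrix((stats::runif(length(x)) < keep) / keep, nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

dropoutBackward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# multi-head scaled-dot-product attention; query and key/value sources may
# differ (cross-attention). p holds Wq,bq,Wk,bk,Wv,bv,Wo,bo.
mhaForward <- function(xq, xkv, p, nHeads) {
  D <- ncol(p$Wq)
  dh <- D / nHeads
  Q <- addRows(xq %*% p$Wq, p$bq)
  K <- addRows(xkv %*% p$Wk, p$bk)
  V <- addRows(xkv %*% p$Wv, p$bv)
  O <- matrix(0, nrow(xq), D)
  A <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmaxRows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- addRows(O %*% p$Wo, p$bo)
  list(out = out, Q = Q, K = K, V = V, A = A, O = O, xq = xq, xkv = xkv)
}

mhaBackward <- function(dOut, cache, p, nHeads) {
  D <- ncol(p$Wq)
  dh <- D / nHeads
  g <- list(Wq = 0 * p$Wq, bq = 0 * p$bq, Wk = 0 * p$Wk, bk = 0 * p$bk,
            Wv = 0 * p$Wv, bv = 0 * p$bv,
            Wo = crossprod(cache$O, dOut), bo = colSums(dOut))
  dO <- tcrossprod(dOut, p$Wo)
  dQ <- 0 * cache$Q; dK <- 0 * cache$K; dV <- 0 * cache$V
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dV[, idx] <- crossprod(A, dOh)
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dS <- softmaxRowsBackward(dA, A) / sqrt(dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  g$Wq <- crossprod(cache$xq, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$xkv, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$xkv, dV); g$bv <- colSums(dV)
  dxq <- tcrossprod(dQ, p$Wq)
  dxkv <- tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(grads = g, dxq = dxq, dxkv = dxkv)
}
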