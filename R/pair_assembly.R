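# Build model inputs from the two diastereomeric complexes: compress the
# per-atom trajectory representations to 20 dimensions, form the mean and
# absolute-difference streams, and attach the solvent descriptor vector.

dataFingerprint <- function(x) {
  sprintf("%dx%d|%.10g|%.10g", nrow(x), ncol(x), sum(x), sum(x * x))
}

standardiseFit <- function(x) {
  ctr <- colMeans(x)
  rawsd <- sqrt(pmax(colMeans(x^2) - ctr^2, 0))
  sc <- ifelse(rawsd < 1e-10, 1, rawsd)
  list(center = ctr, scale = sc, rawsd = rawsd)
}

standardiseApply <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

#' Train a 20-dimensional compressor for per-atom representations
#'
#' Default is a symmetric two-hidden-layer autoencoder
#' (input -> hidden -> latent -> hidden -> input, ReLU hidden units, linear
#' latent and output) minimising squared reconstruction error with Adam;
#' `kind = "pca"` selects an exact principal-component projection instead.
#' Inputs are standardised column-wise before fitting. Train only on
#' training-split atoms: the `fingerprint` slot records the data the
#' compressor saw.
#'
#' @param x numeric matrix of per-atom representations (rows = atoms)
#' @param latentDim latent dimension
#' @param kind `"autoencoder"` or `"pca"`
#' @param seed integer seed (initialisation and batch order)
#' @param hidden autoencoder hidden width
#' @param steps,batchSize,lr autoencoder optimisation controls
#' @return a [Compressor-class]
#' @export
trainCompressor <- function(x, latentDim = 20L, kind = c("autoencoder", "pca"),
                            seed = 1L, hidden = 64L, steps = 200L,
                            batchSize = 32L, lr = 1e-3) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < latentDim)
    stop("need at least latentDim (", latentDim, ") training vectors, got ",
         n, call. = FALSE)
  st <- standardiseFit(x)
  if (all(st$rawsd < 1e-10))
    stop("degenerate (constant) training inputs", call. = FALSE)
  st$rawsd <- NULL
  xs <- standardiseApply(x, st)
  fp <- dataFingerprint(x)
  if (kind == "pca") {
    params <- c(st, list(rotation = dualPca(xs, latentDim, seed)))
  } else {
    params <- c(st, list(net = trainAeNet(xs, latentDim, hidden, steps,
                                          batchSize, lr, seed)))
  }
  new("Compressor", kind = kind, inputDim = as.integer(p),
      latentDim = as.integer(latentDim), params = params, fingerprint = fp)
}

# PCA through the Gram matrix (n x n) so wide inputs stay cheap; rows are
# subsampled (seeded) above nmax.
dualPca <- function(xs, latentDim, seed, nmax = 4000L) {
  if (nrow(xs) > nmax) {
    xs <- xs[withSeed(seed, sample.int(nrow(xs), nmax)), , drop = FALSE]
  }
  gram <- tcrossprod(xs)
  eg <- eigen(gram, symmetric = TRUE)
  k <- latentDim
  lam <- pmax(eg$values[seq_len(k)], 1e-12)
  # columns: principal axes in input space
  crossprod(xs, sweep(eg$vectors[, seq_len(k), drop = FALSE], 2,
                      sqrt(lam), "/"))
}

trainAeNet <- function(xs, latentDim, hidden, steps, batchSize, lr, seed) {
  p <- ncol(xs); n <- nrow(xs)
  withSeed(seed, {
    init <- function(a, b) matrix(stats::runif(a * b, -1, 1) * sqrt(6 / (a + b)), a, b)
    net <- list(W1 = init(p, hidden), b1 = numeric(hidden),
                W2 = init(hidden, latentDim), b2 = numeric(latentDim),
                W3 = init(latentDim, hidden), b3 = numeric(hidden),
                W4 = init(hidden, p), b4 = numeric(p))
    opt <- adamInit(net)
    for (s in seq_len(steps)) {
      idx <- sample.int(n, min(batchSize, n))
      xb <- xs[idx, , drop = FALSE]
      h1 <- pmax(addRows(xb %*% net$W1, net$b1), 0)
      z  <- addRows(h1 %*% net$W2, net$b2)
      h2 <- pmax(addRows(z %*% net$W3, net$b3), 0)
      xhat <- addRows(h2 %*% net$W4, net$b4)
      dxhat <- 2 * (xhat - xb) / length(xb)
      g <- list()
      g$W4 <- crossprod(h2, dxhat); g$b4 <- colSums(dxhat)
      dh2 <- (dxhat %*% t(net$W4)) * (h2 > 0)
      g$W3 <- crossprod(z, dh2); g$b3 <- colSums(dh2)
      dz <- dh2 %*% t(net$W3)
      g$W2 <- crossprod(h1, dz); g$b2 <- colSums(dz)
      dh1 <- (dz %*% t(net$W2)) * (h1 > 0)
      g$W1 <- crossprod(xb, dh1); g$b1 <- colSums(dh1)
      upd <- adamStep(opt, net, g[names(net)], lr)
      net <- upd$params; opt <- upd$state
    }
    net
  })
}

setMethod("encode", "Compressor", function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != object@inputDim)
    stop("input dimension ", ncol(x), " does not match compressor (",
         object@inputDim, ")", call. = FALSE)
  xs <- standardiseApply(x, object@params)
  if (object@kind == "pca") {
    xs %*% object@params$rotation
  } else {
    net <- object@params$net
    h1 <- pmax(addRows(xs %*% net$W1, net$b1), 0)
    addRows(h1 %*% net$W2, net$b2)
  }
})

setMethod("decode", "Compressor", function(object, z) {
  z <- as.matrix(z)
  xs <- if (object@kind == "pca") {
    tcrossprod(z, object@params$rotation)
  } else {
    net <- object@params$net
    h2 <- pmax(addRows(z %*% net$W3, net$b3), 0)
    addRows(h2 %*% net$W4, net$b4)
  }
  sweep(sweep(xs, 2, object@params$scale, "*"), 2, object@params$center, "+")
})

#' Assemble the pair tensors for a diastereomer pair
#'
#' Tokens are the non-hydrogen atoms of the complex (substrate atoms then
#' agent atoms, input order); the R- and S-complex representations must share
#' this ordering. Each token carries the elementwise mean
#' `(z_R + z_S) / 2` and absolute difference `|z_R - z_S|` of the compressed
#' per-atom vectors. Swapping the R and S arguments leaves both streams
#' unchanged: the input is enantiomer-label-free, as the physics requires.
#'
#' @param repR,repS [TrajectoryRep-class] objects (or bare matrices with
#'   matching rownames) for the R- and S-substrate complexes
#' @param compressor a trained [Compressor-class]
#' @return a [PairTensors-class] without solvent attached
#' @export
buildPair <- function(repR, repS, compressor) {
  mR <- if (is(repR, "TrajectoryRep")) repR@rep else as.matrix(repR)
  mS <- if (is(repS, "TrajectoryRep")) repS@rep else as.matrix(repS)
  idsR <- if (is(repR, "TrajectoryRep")) atomIds(repR) else rownames(mR)
  idsS <- if (is(repS, "TrajectoryRep")) atomIds(repS) else rownames(mS)
  if (nrow(mR) != nrow(mS))
    stop("atom-count mismatch between the two diastereomer representations",
         call. = FALSE)
  if (!is.null(idsR) && !is.null(idsS) && !identical(idsR, idsS))
    stop("the two complexes must share an identical atom ordering", call. = FALSE)
  zR <- encode(compressor, mR)
  zS <- encode(compressor, mS)
  new("PairTensors", atoms = if (is.null(idsR)) as.character(seq_len(nrow(mR))) else idsR,
      meanStream = (zR + zS) / 2, diffStream = abs(zR - zS),
      solvent = numeric(0))
}

#' Attach a solvent descriptor vector to pair tensors
#' @param pair a [PairTensors-class]
#' @param solvent numeric descriptor vector
#' @return the updated [PairTensors-class]
#' @export
attachSolvent <- function(pair, solvent) {
  pair@solvent <- as.numeric(solvent)
  pair
}

#' Solvent descriptor vector for a (possibly mixed) solvent system
#'
#' Mixtures are represented by the molar-fraction weighted sum of the pure
#' solvent descriptors.
#'
#' @param ids character vector of solvent ids
#' @param fractions molar fractions (positive, summing to 1 within 1e-6)
#' @param solventTable descriptor table from [loadSolventTable()]
#' @return numeric descriptor vector
#' @export
solventVector <- function(ids, fractions, solventTable) {
  if (abs(sum(fractions) - 1) > 1e-6 || any(fractions <= 0))
    stop("solvent molar fractions must be positive and sum to 1", call. = FALSE)
  miss <- setdiff(ids, rownames(solventTable))
  if (length(miss))
    stop("unknown solvent id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(solventTable[ids, , drop = FALSE])
  as.numeric(crossprod(m, fractions))
}
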