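# The dual-stream attention network: parameter-independent transformer
# stacks over the mean and diff token streams, pooled by cross-attention with
# the embedded solvent vector as the single query, followed by a feedforward
# head. No positional encoding is used, so the output is invariant to a
# consistent permutation of the atom tokens.

#' Model configuration
#'
#' @param n_blocks transformer blocks per stream
#' @param n_heads attention heads (must divide `token_dim`)
#' @param token_dim internal token width
#' @param ff_dim feedforward width inside blocks and head
#' @param dropout dropout rate (training only)
#' @param head_kind `"regression"` or `"classification"`
#' @param n_outputs head outputs (2 for the (m_frac, ee) regression targets,
#'   1 for the single-target variant or classification)
#' @param input_dim compressed token dimension
#' @param solvent_dim solvent descriptor length
#' @param solvent_token additionally append the embedded solvent vector as
#'   an extra token to the cross-attended set (the solvent always acts as
#'   the pooling query; this flag lets it attend to itself as well)
#' @param seed initialisation seed
#' @return a validated config list
#' @export
modelConfig <- function(n_blocks = 2L, n_heads = 4L, token_dim = 64L,
                        ff_dim = 128L, dropout = 0.1,
                        head_kind = c("regression", "classification"),
                        n_outputs = 2L, input_dim = 20L, solvent_dim = 1L,
                        solvent_token = FALSE, seed = 1L) {
  head_kind <- match.arg(head_kind)
  stopifnot(n_blocks >= 1L, n_heads >= 1L, token_dim >= 1L, ff_dim >= 1L,
            dropout >= 0, dropout < 1, n_outputs >= 1L, input_dim >= 1L,
            solvent_dim >= 1L)
  if (token_dim %% n_heads != 0L)
    stop("n_heads must divide token_dim", call. = FALSE)
  if (head_kind == "classification") n_outputs <- 1L
  list(n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
       token_dim = as.integer(token_dim), ff_dim = as.integer(ff_dim),
       dropout = dropout, head_kind = head_kind,
       n_outputs = as.integer(n_outputs), input_dim = as.integer(input_dim),
       solvent_dim = as.integer(solvent_dim),
       solvent_token = isTRUE(solvent_token), seed = as.integer(seed))
}

initAttnParams <- function(D) {
  list(Wq = glorot(D, D), bq = numeric(D), Wk = glorot(D, D), bk = numeric(D),
       Wv = glorot(D, D), bv = numeric(D), Wo = glorot(D, D), bo = numeric(D))
}

initStreamParams <- function(cfg) {
  D <- cfg$token_dim
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    list(ln1 = list(g = rep(1, D), b = numeric(D)),
         attn = initAttnParams(D),
         ln2 = list(g = rep(1, D), b = numeric(D)),
         ffn = list(W1 = glorot(D, cfg$ff_dim), b1 = numeric(cfg$ff_dim),
                    W2 = glorot(cfg$ff_dim, D), b2 = numeric(D)))
  })
  list(emb = list(W = glorot(cfg$input_dim, D), b = numeric(D)),
       blocks = blocks,
       lnf = list(g = rep(1, D), b = numeric(D)))
}

initHeadParams <- function(cfg) {
  list(W1 = glorot(cfg$token_dim, cfg$ff_dim), b1 = numeric(cfg$ff_dim),
       W2 = glorot(cfg$ff_dim, cfg$n_outputs), b2 = numeric(cfg$n_outputs))
}

#' Initialise a dual-stream model
#' @param config from [modelConfig()]
#' @return a [DualStreamModel-class]
#' @export
initModel <- function(config) {
  D <- config$token_dim
  params <- withSeed(config$seed, list(
    mean = initStreamParams(config),
    diff = initStreamParams(config),
    solv = list(W = glorot(config$solvent_dim, D), b = numeric(D)),
    cross = initAttnParams(D),
    head = initHeadParams(config)))
  new("DualStreamModel", config = config, params = params, frozen = character(0))
}

streamForward <- function(x, sp, cfg, train) {
  cache <- list(x = x)
  e <- addRows(x %*% sp$emb$W, sp$emb$b)
  cache$blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    bp <- sp$blocks[[b]]
    ln1 <- lnForward(e, bp$ln1$g, bp$ln1$b)
    at <- mhaForward(ln1$y, ln1$y, bp$attn, cfg$n_heads)
    dr1 <- dropoutForward(at$out, cfg$dropout, train)
    e1 <- e + dr1$y
    ln2 <- lnForward(e1, bp$ln2$g, bp$ln2$b)
    h <- pmax(addRows(ln2$y %*% bp$ffn$W1, bp$ffn$b1), 0)
    f <- addRows(h %*% bp$ffn$W2, bp$ffn$b2)
    dr2 <- dropoutForward(f, cfg$dropout, train)
    cache$blocks[[b]] <- list(ln1 = ln1, at = at, dr1 = dr1, e = e,
                              ln2 = ln2, h = h, dr2 = dr2, e1 = e1)
    e <- e1 + dr2$y
  }
  lnf <- lnForward(e, sp$lnf$g, sp$lnf$b)
  cache$lnf <- lnf
  cache$z <- lnf$y
  cache
}

streamBackward <- function(dz, cache, sp, cfg) {
  g <- list(emb = list(W = 0 * sp$emb$W, b = 0 * sp$emb$b),
            blocks = vector("list", cfg$n_blocks), lnf = NULL)
  lb <- lnBackward(dz, cache$lnf, sp$lnf$g)
  g$lnf <- list(g = lb$dg, b = lb$db)
  de <- lb$dx
  for (b in rev(seq_len(cfg$n_blocks))) {
    bp <- sp$blocks[[b]]
    bc <- cache$blocks[[b]]
    df <- dropoutBackward(de, bc$dr2$mask)
    gW2 <- crossprod(bc$h, df); gb2 <- colSums(df)
    dh <- tcrossprod(df, bp$ffn$W2) * (bc$h > 0)
    gW1 <- crossprod(bc$ln2$y, dh); gb1 <- colSums(dh)
    dln2y <- tcrossprod(dh, bp$ffn$W1)
    lb2 <- lnBackward(dln2y, bc$ln2, bp$ln2$g)
    de1 <- de + lb2$dx
    dat <- dropoutBackward(de1, bc$dr1$mask)
    mb <- mhaBackward(dat, bc$at, bp$attn, cfg$n_heads)
    lb1 <- lnBackward(mb$dxq + mb$dxkv, bc$ln1, bp$ln1$g)
    g$blocks[[b]] <- list(ln1 = list(g = lb1$dg, b = lb1$db),
                          attn = mb$grads,
                          ln2 = list(g = lb2$dg, b = lb2$db),
                          ffn = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
    de <- de1 + lb1$dx
  }
  g$emb$W <- crossprod(cache$x, de)
  g$emb$b <- colSums(de)
  list(grads = g, dx = tcrossprod(de, sp$emb$W))
}

#' Forward pass of the dual-stream model
#'
#' @param model a [DualStreamModel-class]
#' @param pair a [PairTensors-class] with solvent attached
#' @param train apply dropout (training mode)?
#' @param recordAttention also return row-normalised attention matrices per
#'   stream, block and head, plus the cross-attention row?
#' @param keepCache keep intermediate activations (needed for backprop)?
#' @return list with `output` (raw head output), `probability`
#'   (classification head only), and optionally `attention` and `cache`
#' @export
modelForward <- function(model, pair, train = FALSE, recordAttention = FALSE,
                         keepCache = FALSE) {
  cfg <- model@config
  p <- model@params
  if (nrow(pair@meanStream) < 1L) stop("empty token stream", call. = FALSE)
  if (length(pair@solvent) != cfg$solvent_dim)
    stop("solvent vector length ", length(pair@solvent),
         " does not match config (", cfg$solvent_dim, ")", call. = FALSE)
  if (ncol(pair@meanStream) != cfg$input_dim)
    stop("token dimension mismatch", call. = FALSE)
  cm <- streamForward(pair@meanStream, p$mean, cfg, train)
  cd <- streamForward(pair@diffStream, p$diff, cfg, train)
  solv <- matrix(pair@solvent, 1)
  qs <- addRows(solv %*% p$solv$W, p$solv$b)
  zc <- rbind(cm$z, cd$z)
  if (isTRUE(cfg$solvent_token)) zc <- rbind(zc, qs)
  cx <- mhaForward(qs, zc, p$cross, cfg$n_heads)
  pooled <- cx$out
  h <- pmax(addRows(pooled %*% p$head$W1, p$head$b1), 0)
  out <- addRows(h %*% p$head$W2, p$head$b2)
  res <- list(output = as.numeric(out))
  if (cfg$head_kind == "classification")
    res$probability <- 1 / (1 + exp(-res$output))
  if (recordAttention) {
    getA <- function(cache) lapply(cache$blocks, function(b) {
      lapply(b$at$A, identity)
    })
    res$attention <- list(
      streams = list(mean = getA(cm), diff = getA(cd)),
      cross = cx$A,
      atoms = pair@atoms)
  }
  if (keepCache)
    res$cache <- list(cm = cm, cd = cd, zc = zc, solv = solv, qs = qs,
                      cx = cx, pooled = pooled, h = h, Tm = nrow(cm$z))
  res
}

# gradient of the loss w.r.t. all parameters, given d(loss)/d(raw output)
modelBackward <- function(model, cache, dOut) {
  cfg <- model@config
  p <- model@params
  dOut <- matrix(dOut, 1)
  g <- list()
  g$head <- list(W1 = NULL, b1 = NULL, W2 = crossprod(cache$h, dOut),
                 b2 = colSums(dOut))
  dh <- tcrossprod(dOut, p$head$W2) * (cache$h > 0)
  g$head$W1 <- crossprod(cache$pooled, dh)
  g$head$b1 <- colSums(dh)
  dpooled <- tcrossprod(dh, p$head$W1)
  mb <- mhaBackward(dpooled, cache$cx, p$cross, cfg$n_heads)
  g$cross <- mb$grads
  dqs <- mb$dxq
  dxkv <- mb$dxkv
  if (isTRUE(cfg$solvent_token)) {
    # the appended solvent token also feeds the key/value path
    dqs <- dqs + dxkv[nrow(dxkv), , drop = FALSE]
    dxkv <- dxkv[-nrow(dxkv), , drop = FALSE]
  }
  g$solv <- list(W = crossprod(cache$solv, dqs), b = colSums(dqs))
  Tm <- cache$Tm
  dzm <- dxkv[seq_len(Tm), , drop = FALSE]
  dzd <- dxkv[-seq_len(Tm), , drop = FALSE]
  sm <- streamBackward(dzm, cache$cm, p$mean, cfg)
  sd <- streamBackward(dzd, cache$cd, p$diff, cfg)
  g$mean <- sm$grads
  g$diff <- sd$grads
  g[c("mean", "diff", "solv", "cross", "head")]
}

#' Predict a single pair with one model
#'
#' @param model a [DualStreamModel-class]
#' @param pair a [PairTensors-class]
#' @return the probability (classification head) or the raw output vector
#' @export
predictPair <- function(model, pair) {
  r <- modelForward(model, pair)
  if (model@config$head_kind == "classification") r$probability else r$output
}

#' Replace the model head, freezing everything else
#'
#' All non-head parameters are kept bit-identical and marked frozen;
#' subsequent fine-tuning updates only the (re-initialised) head.
#'
#' @param model a trained [DualStreamModel-class]
#' @param head_kind new head kind
#' @param seed head initialisation seed
#' @return the model with the new head
#' @export
swapHead <- function(model, head_kind = "classification", seed = 1L) {
  cfg <- model@config
  cfg$head_kind <- head_kind
  cfg$n_outputs <- if (head_kind == "classification") 1L else cfg$n_outputs
  model@config <- cfg
  model@params$head <- withSeed(seed, initHeadParams(cfg))
  model@frozen <- c("mean", "diff", "solv", "cross")
  model
}

#' Fingerprint of the non-head parameters (freeze-contract checks)
#' @param model a [DualStreamModel-class]
#' @return character digest of all non-head parameter values
#' @export
backboneFingerprint <- function(model) {
  v <- flattenTree(model@params[c("mean", "diff", "solv", "cross")])
  paste(length(v), format(sum(v), digits = 17), format(sum(v^2), digits = 17),
        format(sum(v^3), digits = 17))
}

#' Ensemble prediction
#'
#' Mean probability (or raw output) across ensemble members; per-member
#' outputs are retained so the ensemble spread can be reported.
#'
#' @param models non-empty list of [DualStreamModel-class] objects
#' @param pair a [PairTensors-class]
#' @return list with `mean` and `members`
#' @export
ensemblePredict <- function(models, pair) {
  if (!length(models)) stop("empty ensemble", call. = FALSE)
  member <- vapply(models, function(m) predictPair(m, pair)[1], numeric(1))
  list(mean = mean(member), members = member)
}
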