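test_that("model config validates its dimensions", {
  expect_error(modelConfig(n_heads = 3L, token_dim = 64L), "divide")
  cfg <- modelConfig(head_kind = "classification", n_outputs = 5L)
  expect_equal(cfg$n_outputs, 1L)   # classification is single-output
})

test_that("classification output is a probability and forward is deterministic", {
  pair <- randomPairTensors(seed = 1L)
  cfg <- smallModelConfig(head_kind = "classification")
  m <- initModel(cfg)
  r1 <- modelForward(m, pair)
  expect_gte(r1$probability, 0)
  expect_lte(r1$probability, 1)
  r2 <- modelForward(m, pair)
  expect_identical(r1$output, r2$output)   # bit-for-bit reproducible
})

test_that("output is invariant to a consistent token permutation", {
  set.seed(14)
  pair <- randomPairTensors(nTokens = 7L, seed = 2L)
  m <- initModel(smallModelConfig())
  base <- modelForward(m, pair)$output
  for (rep in 1:3) {
    perm <- sample(7)
    p2 <- new("PairTensors", atoms = pair@atoms[perm],
              meanStream = pair@meanStream[perm, ],
              diffStream = pair@diffStream[perm, ],
              solvent = pair@solvent)
    expect_equal(modelForward(m, p2)$output, base, tolerance = 1e-6)
  }
})

test_that("the diff stream is live: perturbing it changes the output", {
  pair <- randomPairTensors(seed = 3L)
  zero <- new("PairTensors", atoms = pair@atoms,
              meanStream = pair@meanStream,
              diffStream = 0 * pair@diffStream, solvent = pair@solvent)
  m <- initModel(smallModelConfig())
  o0 <- modelForward(m, zero)$output
  pert <- zero
  pert@diffStream[1, 1] <- 0.5
  expect_gt(max(abs(modelForward(m, pert)$output - o0)), 1e-8)
})

test_that("attention rows are probability distributions at every head", {
  pair <- randomPairTensors(nTokens = 5L, seed = 4L)
  m <- initModel(smallModelConfig(n_blocks = 2L))
  att <- modelForward(m, pair, recordAttention = TRUE)$attention
  for (stream in att$streams) {
    expect_length(stream, 2L)   # per block
    for (block in stream) {
      expect_length(block, 2L)  # per head
      for (A in block) {
        expect_true(all(A >= 0))
        expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
      }
    }
  }
  # cross-attention rows too
  for (A in att$cross) expect_equal(rowSums(A), 1, tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  pair <- randomPairTensors(seed = 5L)
  m <- initModel(smallModelConfig())
  fw <- modelForward(m, pair, keepCache = TRUE)
  grad <- chirsep:::modelBackward(m, fw$cache, c(1, 0))
  flat <- chirsep:::flattenTree(m@params)
  gflat <- chirsep:::flattenTree(grad)
  lossAt <- function(vec) {
    mm <- m
    mm@params <- chirsep:::unflattenTree(vec, m@params)
    modelForward(mm, pair)$output[1]
  }
  set.seed(15)
  idx <- sample(length(flat), 30)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (lossAt(up) - lossAt(dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(num, gflat[idx], tolerance = 1e-6)
})

test_that("head swap freezes the backbone bit-identically", {
  pair <- randomPairTensors(seed = 6L)
  m <- initModel(smallModelConfig())
  fpBefore <- backboneFingerprint(m)
  m2 <- swapHead(m, "classification", seed = 99L)
  expect_identical(backboneFingerprint(m2), fpBefore)
  expect_identical(m2@params$mean, m@params$mean)
  expect_setequal(m2@frozen, c("mean", "diff", "solv", "cross"))
  # head output dimension changes 2 -> 1
  expect_length(modelForward(m, pair)$output, 2L)
  expect_length(modelForward(m2, pair)$output, 1L)
})

test_that("fine-tuning gradient steps leave frozen weights unchanged", {
  set.seed(16)
  pairs <- lapply(1:8, function(i) randomPairTensors(seed = 20L + i))
  labels <- rep(c(TRUE, FALSE), 4)
  m <- initModel(smallModelConfig())
  fp <- backboneFingerprint(m)
  ft <- stage2Finetune(m, pairs, labels, steps = 25L, seed = 2L)
  expect_identical(backboneFingerprint(ft$model), fp)
})

test_that("ensembles average member probabilities", {
  pair <- randomPairTensors(seed = 7L)
  cfgc <- smallModelConfig(head_kind = "classification")
  m1 <- initModel(cfgc)
  cfg2 <- cfgc; cfg2$seed <- 77L
  m2 <- initModel(cfg2)
  single <- ensemblePredict(list(m1), pair)
  expect_equal(single$mean, predictPair(m1, pair))
  same <- ensemblePredict(rep(list(m1), 5), pair)
  expect_equal(sd(same$members), 0)
  both <- ensemblePredict(list(m1, m2), pair)
  expect_equal(both$mean, mean(c(predictPair(m1, pair), predictPair(m2, pair))))
  expect_error(ensemblePredict(list(), pair), "empty")
})

test_that("the solvent-as-token variant stays differentiable and distinct", {
  pair <- randomPairTensors(seed = 8L)
  m <- initModel(smallModelConfig(solvent_token = TRUE))
  base <- initModel(smallModelConfig())
  expect_false(isTRUE(all.equal(modelForward(m, pair)$output,
                                modelForward(base, pair)$output)))
  fw <- modelForward(m, pair, keepCache = TRUE)
  grad <- chirsep:::modelBackward(m, fw$cache, c(0, 1))
  flat <- chirsep:::flattenTree(m@params)
  gflat <- chirsep:::flattenTree(grad)
  lossAt <- function(vec) {
    mm <- m
    mm@params <- chirsep:::unflattenTree(vec, m@params)
    modelForward(mm, pair)$output[2]
  }
  set.seed(44)
  idx <- sample(length(flat), 25)
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + 1e-5
    dn <- flat; dn[i] <- dn[i] - 1e-5
    (lossAt(up) - lossAt(dn)) / 2e-5
  }, numeric(1))
  expect_equal(num, gflat[idx], tolerance = 1e-6)
})
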