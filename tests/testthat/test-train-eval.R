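test_that("figures of merit follow their definitions", {
  f <- figuresOfMerit(20, 100, 0.75, 0.25)
  expect_equal(f$m_frac, 0.2)
  expect_equal(f$ee, 0.5)
  expect_equal(f$z, 0.1)
  # ideal resolution of a racemic feed
  ideal <- figuresOfMerit(0.5, 1, 1, 0)
  expect_equal(ideal$z, 0.5)
  expect_error(figuresOfMerit(110, 100, 0.5, 0.5), "exceed")
})

test_that("success labels use the stated strict/non-strict thresholds", {
  df <- data.frame(m_frac = c(0.21, 0.19, 0.20, 0.5, 0.25),
                   ee = c(0.26, 0.90, 0.25, 0.6, 0.25),
                   full_dissolution = c(NA, NA, NA, TRUE, TRUE))
  lab <- labelRecords(df)
  expect_equal(lab$retrospective_hit, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(lab$low_noise, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  # z = 0.30 >= 0.25 with full dissolution
  expect_true(lab$prospective_hit[4])
  expect_false(lab$prospective_hit[5])   # z = 0.0625
  # a retrospective hit is always in the low-noise subset
  expect_true(all(lab$low_noise[lab$retrospective_hit]))
})

test_that("group k-fold never splits a racemate and balances record counts", {
  ids <- rep(paste0("r", 1:10), times = c(8, 8, 5, 5, 4, 4, 3, 3, 2, 2))
  plan <- groupKFold(ids, k = 5L, seed = 3L)
  expect_equal(plan$k, 5L)
  # defining property: each racemate in exactly one fold
  tab <- table(ids, plan$fold)
  expect_true(all(rowSums(tab > 0) == 1))
  # equal-count case: 2 racemates per fold
  even <- rep(paste0("q", 1:10), each = 4)
  expect_true(all(table(groupKFold(even, k = 5L, seed = 2L)$racemateFold) == 2))
  # determinism and seed sensitivity
  expect_identical(plan, groupKFold(ids, k = 5L, seed = 3L))
  # train/test racemate sets are disjoint for every fold
  for (f in 1:5) {
    expect_length(intersect(unique(ids[plan$fold == f]),
                            unique(ids[plan$fold != f])), 0)
  }
  expect_error(groupKFold(paste0("r", 1:4), k = 5L), "at least")
})

test_that("balanced sampler yields ~50% hits over many batches", {
  labels <- c(rep(TRUE, 30), rep(FALSE, 970))
  set.seed(4)
  prop <- mean(vapply(1:1000, function(b)
    mean(labels[sampleBalancedIndices(labels, 32L)]), numeric(1)))
  expect_gt(prop, 0.45)
  expect_lt(prop, 0.55)
  expect_error(sampleBalancedIndices(rep(TRUE, 10), 4L), "both classes")
})

test_that("enrichment factor matches the counting oracle and decays to one", {
  set.seed(5)
  for (rep in 1:5) {
    N <- 100
    scores <- rnorm(N)
    labels <- rep(FALSE, N)
    labels[sample(N, 8)] <- TRUE
    ec <- enrichmentCurve(scores, labels)
    expect_equal(ec$ef[N], 1.0)   # EF(N) = 1 by construction
    for (n in c(5, 10, 37)) {
      expect_equal(ec$ef[n], oracleEnrichment(scores, labels, n))
    }
    expect_true(all(ec$ef <= N / sum(labels) + 1e-12))
    expect_true(all(ec$ef >= 0))
  }
  # perfect ranking: EF at n = H is N/H
  lab <- c(rep(TRUE, 8), rep(FALSE, 92))
  ec <- enrichmentCurve(seq(100, 1), lab)
  expect_equal(ec$ef[8], 100 / 8)
  # worked example: 4 hits in top 10 of N=100 with H=8
  sc <- c(seq(50, 41), seq(10, 1, length.out = 90))
  lb <- rep(FALSE, 100); lb[c(1, 3, 5, 7)] <- TRUE; lb[95:98] <- TRUE
  expect_equal(enrichmentCurve(sc, lb)$ef[10], 4 / (10 * 8 / 100))  # = 5
  expect_error(enrichmentCurve(sc, rep(FALSE, 100)), "zero hits")
})

test_that("average precision matches the pairwise oracle and closed forms", {
  # perfect ranking
  expect_equal(averagePrecision(10:1, c(rep(TRUE, 3), rep(FALSE, 7))), 1.0)
  # single hit ranked last of N
  N <- 20
  expect_equal(averagePrecision(seq(N, 1), c(rep(FALSE, N - 1), TRUE)), 1 / N)
  set.seed(6)
  for (rep in 1:10) {
    scores <- rnorm(50)
    labels <- runif(50) < 0.2
    if (!any(labels)) labels[1] <- TRUE
    expect_equal(averagePrecision(scores, labels),
                 oracleAveragePrecision(scores, labels))
  }
})

test_that("EF and AP are invariant under monotone score transforms", {
  set.seed(7)
  scores <- rnorm(80)
  labels <- runif(80) < 0.15
  labels[1] <- TRUE
  mono <- function(x) exp(0.3 * x) + 5
  expect_equal(enrichmentCurve(scores, labels)$ef,
               enrichmentCurve(mono(scores), labels)$ef)
  expect_equal(averagePrecision(scores, labels),
               averagePrecision(mono(scores), labels))
})

test_that("random scores give mean EF near one at every depth", {
  set.seed(8)
  N <- 200; H <- 20
  labels <- c(rep(TRUE, H), rep(FALSE, N - H))
  at <- c(10, 50, 100)
  efs <- t(vapply(1:200, function(s) enrichmentCurve(rnorm(N), labels, at)$ef,
                  numeric(3)))
  for (k in seq_along(at)) {
    n <- at[k]
    se <- sqrt(n * (H / N) * (1 - H / N)) / (n * H / N) / sqrt(200)
    expect_lt(abs(mean(efs[, k]) - 1), 3 * se)
  }
})

test_that("stage-1 training overfits a small fixture and is seed-stable", {
  set.seed(9)
  pairs <- lapply(1:10, function(i) randomPairTensors(seed = 30L + i))
  targets <- cbind(runif(10), runif(10))
  m <- initModel(smallModelConfig())
  run <- function() stage1Train(m, pairs, targets, steps = 250L,
                                batchSize = 5L, lr = 3e-3, seed = 12L,
                                valFraction = 0)
  r1 <- run()
  finalLoss <- mean(tail(r1$loss, 10))
  expect_lt(finalLoss, 0.1 * r1$loss[1])
  r2 <- run()
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$model@params, r2$model@params)
  # missing tensors are named
  expect_error(stage1Train(m, c(pairs[1:3], list(NULL), pairs[5:10]),
                           targets, steps = 2L), "record")
  expect_error(stage1Train(m, list(), targets[0, ], steps = 2L), "empty")
})

test_that("stage-2 fine-tuning separates a linearly separable fixture", {
  set.seed(10)
  # pairs whose diff stream carries a clean class offset
  mk <- function(shift, seed) {
    p <- randomPairTensors(seed = seed)
    p@diffStream <- abs(p@diffStream * 0.1 + shift)
    p
  }
  pairs <- c(lapply(1:10, function(i) mk(2, 40 + i)),
             lapply(1:10, function(i) mk(0.01, 60 + i)))
  labels <- rep(c(TRUE, FALSE), each = 10)
  m <- initModel(smallModelConfig())
  ft <- stage2Finetune(m, pairs, labels, steps = 300L, lr = 2e-2, seed = 3L)
  prob <- vapply(pairs, function(p) predictPair(ft$model, p), numeric(1))
  # AUC = 1: every hit scores above every non-hit
  expect_gt(min(prob[labels]), max(prob[!labels]))
  expect_error(stage2Finetune(m, pairs, rep(TRUE, 20)), "both classes")
})

test_that("agent ranking takes the max across solvents, stably", {
  set.seed(11)
  cfg <- smallModelConfig(head_kind = "classification")
  m <- initModel(cfg)
  pairs <- lapply(1:6, function(i) randomPairTensors(seed = 70L + i))
  agents <- rep(c("agtB", "agtA", "agtC"), each = 2)
  solvents <- rep(c("s1", "s2"), 3)
  rk <- rankAgents(list(m), pairs, agents, solvents)
  prob <- scoreRecords(list(m), pairs)
  expect_equal(rk$score[rk$agent_id == "agtA"], max(prob[3:4]))
  expect_equal(rk$score, sort(rk$score, decreasing = TRUE))
  # permuting solvent order does not change the ranking
  perm <- c(2, 1, 4, 3, 6, 5)
  rk2 <- rankAgents(list(m), pairs[perm], agents[perm], solvents[perm])
  expect_equal(rk2$agent_id, rk$agent_id)
  expect_equal(rk2$score, rk$score)
  # single solvent: ranking equals per-solvent ordering
  one <- which(solvents == "s1")
  rk1 <- rankAgents(list(m), pairs[one], agents[one], solvents[one])
  expect_equal(rk1$agent_id, agents[one][order(-prob[one])])
  expect_error(rankAgents(list(m), list(), character(0), character(0)),
               "empty")
})
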