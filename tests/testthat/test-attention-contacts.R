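test_that("contact extraction is a symmetric heavy-atom cutoff filter", {
  cx <- saltComplex(
    molecule3d(c("C", "C", "H"),
               rbind(c(0, 0, 0), c(0, 0, 3.0), c(0, 1, 0)),
               role = "substrate"),
    molecule3d("O", matrix(c(0, 0, 7.0), 1), role = "resolving_agent",
               atomIds = "agt_1"))
  ct <- findContacts(cx, cutoff = 3.5)
  # the 3.0 A pair is a neighbour; the 4.0 A pair is not; H is no token
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$atom_i, "sub_1")
  expect_equal(ct$atom_j, "sub_2")
  expect_false(ct$intermolecular)
  # symmetry: pairs are stored unordered (i < j), both directions queried
  nb <- with(ct, cbind(i, j))
  expect_true(all(nb[, 1] < nb[, 2]))
  # intermolecular flagging at a closer agent
  cx2 <- saltComplex(cx@substrate,
                     molecule3d("O", matrix(c(0, 0, 5.0), 1),
                                role = "resolving_agent", atomIds = "agt_1"))
  ct2 <- findContacts(cx2, cutoff = 3.5)
  expect_true(any(ct2$intermolecular))
  # unmapped atoms are listed
  expect_error(findContacts(cx, tokens = c("sub_1")), "sub_2")
})

uniformAttention <- function(Tn, nBlocks = 1L, nHeads = 2L) {
  A <- matrix(1 / Tn, Tn, Tn)
  list(streams = list(mean = rep(list(rep(list(A), nHeads)), nBlocks),
                      diff = rep(list(rep(list(A), nHeads)), nBlocks)),
       cross = list(matrix(1 / (2 * Tn), 1, 2 * Tn)),
       atoms = paste0("t", seq_len(Tn)))
}

test_that("uniform attention gives neighbour and non-neighbour ratios of 1", {
  att <- uniformAttention(6L)
  contacts <- data.frame(i = c(1, 2), j = c(2, 5),
                         atom_i = c("t1", "t2"), atom_j = c("t2", "t5"),
                         distance = c(1.5, 3.0), intermolecular = FALSE)
  st <- headStats(att, contacts)
  expect_equal(st$ratio_neighbour, rep(1, nrow(st)))
  expect_equal(st$ratio_nonneighbour, rep(1, nrow(st)))
  expect_error(headStats(att, contacts[0, ]), "empty")
})

test_that("a concentrated attention matrix reproduces hand-derived ratios", {
  # T = 4 tokens, neighbours {1,2} and {3,4}: every row puts all its mass on
  # its neighbour, so the symmetrised mean over the 4 ordered neighbour
  # cells is 1 and the ratio to the uniform baseline 1/T is T = 4
  Tn <- 4L
  A <- matrix(0, Tn, Tn)
  A[1, 2] <- 1; A[2, 1] <- 1; A[3, 4] <- 1; A[4, 3] <- 1
  att <- list(streams = list(mean = list(list(A))),
              cross = list(), atoms = paste0("t", 1:4))
  contacts <- data.frame(i = c(1, 3), j = c(2, 4),
                         atom_i = c("t1", "t3"), atom_j = c("t2", "t4"),
                         distance = 1.5, intermolecular = FALSE)
  st <- headStats(att, contacts)
  expect_equal(st$mean_neighbour, 1)
  expect_equal(st$ratio_neighbour, 4)
  expect_equal(st$mean_nonneighbour, 0)
  expect_equal(st$ratio_nonneighbour, 0)
})

test_that("head statistics are invariant under joint token relabelling", {
  set.seed(21)
  Tn <- 5L
  A <- matrix(runif(Tn * Tn), Tn)
  A <- A / rowSums(A)
  att <- list(streams = list(mean = list(list(A))), cross = list(),
              atoms = paste0("t", 1:Tn))
  contacts <- data.frame(i = c(1, 2), j = c(3, 5), atom_i = NA, atom_j = NA,
                         distance = 2, intermolecular = FALSE)
  s1 <- headStats(att, contacts)
  perm <- c(3, 1, 5, 2, 4)   # token k -> position perm[k]
  P <- diag(Tn)[perm, ]
  att2 <- list(streams = list(mean = list(list(t(P) %*% A %*% P))),
               cross = list(), atoms = paste0("t", 1:Tn))
  # old token k sits at new position perm[k]
  contacts2 <- transform(contacts, i = pmin(perm[i], perm[j]),
                         j = pmax(perm[i], perm[j]))
  s2 <- headStats(att2, contacts2)
  expect_equal(s2$mean_neighbour, s1$mean_neighbour)
  expect_equal(s2$mean_nonneighbour, s1$mean_nonneighbour)
})

test_that("reference-atom profiles renormalise and flag ties", {
  att <- uniformAttention(5L)
  pr <- referenceAtomProfile(att, "t2")
  expect_equal(sum(pr$profile), 1)
  expect_true(pr$tied)
  expect_setequal(pr$argmax, paste0("t", c(1, 3, 4, 5)))
  # one dominant entry wins
  A <- matrix(1 / 5, 5, 5)
  A[2, 4] <- 10; A <- A / rowSums(A)
  att$streams$mean[[1]][[1]] <- A
  pr2 <- referenceAtomProfile(att, "t2")
  expect_equal(pr2$argmax, "t4")
  expect_false(pr2$tied)
  expect_equal(sum(pr2$profile), 1)
})

test_that("untrained models show no neighbour preference on average", {
  pair <- chiralPairFixture()
  comp <- cached("attnComp", {
    rows <- rbind(staticTrajRep(pair$R), staticTrajRep(pair$S))
    set.seed(32)
    rows <- rbind(rows, rows + matrix(rnorm(length(rows), sd = 0.05), nrow(rows)))
    trainCompressor(rows, kind = "pca")
  })
  pt <- attachSolvent(buildPair(staticTrajRep(pair$R), staticTrajRep(pair$S),
                                comp), rep(0, 4))
  contacts <- findContacts(pair$R, cutoff = 3.5)
  ratios <- vapply(1:10, function(s) {
    cfg <- smallModelConfig()
    cfg$seed <- 500L + s
    m <- initModel(cfg)
    att <- modelForward(m, pt, recordAttention = TRUE)$attention
    st <- headStats(att, contacts)
    c(mean(st$ratio_neighbour), mean(st$ratio_nonneighbour))
  }, numeric(2))
  expect_lt(abs(mean(ratios[1, ]) - 1), 0.15)
  expect_lt(abs(mean(ratios[2, ]) - 1), 0.15)
})
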