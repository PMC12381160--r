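# Programmatic fixtures shared across test files. Everything is generated in
# code; a small cache avoids re-generating the heavier objects per test.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

waterXyzLines <- function() {
  c("3", "water",
    "O 0.0 0.0 0.1173",
    "H 0.0 0.7572 -0.4692",
    "H 0.0 -0.7572 -0.4692")
}

writeTempFile <- function(lines, ext = ".xyz") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small diastereomer pair with a chiral agent
chiralPairFixture <- function() {
  cached("chiralPair",
         makeChiralComplex(c("CH3", "NH2", "OH", "H"),
                           c("COOH", "CH3", "F", "H")))
}

achiralPairFixture <- function() {
  cached("achiralPair",
         makeChiralComplex(c("CH3", "NH2", "OH", "H"), "achiral_planar"))
}

# random pair tensors for model-level tests
randomPairTensors <- function(nTokens = 6L, latent = 20L, solventDim = 4L,
                              seed = 1L) {
  set.seed(seed)
  new("PairTensors", atoms = paste0("a", seq_len(nTokens)),
      meanStream = matrix(rnorm(nTokens * latent), nTokens),
      diffStream = abs(matrix(rnorm(nTokens * latent), nTokens)),
      solvent = rnorm(solventDim))
}

smallModelConfig <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 1L, n_heads = 2L, token_dim = 8L, ff_dim = 12L,
         dropout = 0, solvent_dim = 4L, seed = 3L),
    list(...))
  do.call(modelConfig, args)
}

# trajectory-style (mean||std) matrix from a single static geometry
staticTrajRep <- function(cx) {
  r <- snapshotRepresentation(cx)
  cbind(r, 0 * r)
}

# small planted-signal dataset shared by pipeline-level unit tests
smallDatasetFixture <- function() {
  cached("smallDataset",
         generateDataset(nRacemates = 8L, nAgents = 5L, nSolvents = 2L,
                         baseRate = 0.10, framesPerPair = 6L, seed = 21L))
}

# an external-weights exchange file matching a 3-atom molecule
externalWeightsLines <- function() {
  c("# chirsep weights exchange format",
    "NATOMS 3",
    "ELEMENTS",
    "O H H",
    "CHARGES",
    "-0.4 0.2 0.2",
    "POPULATIONS",
    "1.9 4.5 0.0",
    "1.0 0.0 0.0",
    "1.0 0.0 0.0",
    "OVERLAP_SIGMA",
    "1 2 0.55",
    "1 3 0.55",
    "2 3 0.10",
    "OVERLAP_PI",
    "1 2 0.20",
    "OVERLAP_DELTA",
    "END")
}

waterComplexFixture <- function() {
  # water "substrate" + planar agent; only used for provider-level tests
  sub <- molecule3d(c("O", "H", "H"),
                    rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                          c(0, -0.7572, -0.4692)),
                    role = "substrate")
  agt <- molecule3d("O", matrix(c(0, 0, 3.2), 1), role = "resolving_agent",
                    atomIds = "agt_1")
  saltComplex(sub, agt)
}
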