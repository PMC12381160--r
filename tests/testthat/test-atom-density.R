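test_that("the radial Gaussian matches its closed form and integrates to 1", {
  # peak value at r = d
  expect_equal(gaussianDensity(2.0, 2.0), 1 / (0.0825 * sqrt(2 * pi)))
  expect_equal(gaussianDensity(2.0, 2.0), 4.8358, tolerance = 1e-4)
  # far tail is numerically zero
  expect_lt(gaussianDensity(2.0, 7.9), 1e-300)
  # quadrature oracle: unit mass over the real line
  q <- stats::integrate(function(r) gaussianDensity(3.1, r), -Inf, Inf)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("radial grid spans 0.7 to 8 Angstrom in 160 even bins", {
  g <- radialGrid()
  expect_equal(g$n_bins, 160L)
  expect_equal(g$centers[1], 0.7)
  expect_equal(g$centers[160], 8.0)
  expect_equal(length(unique(round(diff(g$centers), 12))), 1L)
})

test_that("two-body profiles match the brute-force oracle and are linear", {
  set.seed(11)
  co <- matrix(rnorm(24, sd = 2), 8)
  om <- abs(matrix(rnorm(64), 8)); om <- om + t(om); diag(om) <- 0
  g <- radialGrid()
  for (i in c(1, 4, 8)) {
    expect_equal(a2Profile(co, om, i, g), oracleA2(co, om, i, g$centers),
                 tolerance = 1e-12)
  }
  # no neighbours within cutoff
  far <- rbind(c(0, 0, 0), c(0, 0, 50))
  expect_equal(a2Profile(far, matrix(1, 2, 2), 1, g), numeric(160))
  # single neighbour, unit weight: peak near d, unit quadrature mass
  two <- rbind(c(0, 0, 0), c(0, 0, 3))
  prof <- a2Profile(two, matrix(1, 2, 2) - diag(2), 1, g)
  expect_equal(g$centers[which.max(prof)], 3.0, tolerance = diff(g$centers[1:2]))
  expect_equal(sum(prof) * diff(g$centers[1:2]), 1, tolerance = 1e-3)
  # two equidistant unit-weight neighbours double the profile
  three <- rbind(c(0, 0, 0), c(0, 0, 3), c(0, 3, 0))
  omu <- matrix(1, 3, 3) - diag(3)
  expect_equal(a2Profile(three, omu, 1, g), 2 * prof, tolerance = 1e-12)
  # linearity in the weights
  expect_equal(a2Profile(co, 3 * om, 1, g), 3 * a2Profile(co, om, 1, g))
})

test_that("three-body profiles match the brute-force double-loop oracle", {
  set.seed(12)
  g <- radialGrid()
  # printed 4-atom fixture
  co <- rbind(c(0, 0, 0), c(1.2, 0.1, -0.3), c(-0.8, 1.1, 0.4),
              c(0.3, -1.4, 1.0))
  om <- matrix(c(0, .5, .2, .8, .5, 0, .3, .1, .2, .3, 0, .6, .8, .1, .6, 0), 4)
  for (fn in c("cos", "sin")) {
    for (i in 1:4) {
      expect_equal(a3Profile(co, om, i, fn, g),
                   oracleA3(co, om, i, g$centers, fn), tolerance = 1e-11)
    }
  }
  # fewer than 2 neighbours: zero
  expect_equal(a3Profile(rbind(c(0, 0, 0), c(0, 0, 2)),
                         matrix(1, 2, 2) - diag(2), 1, "cos", g), numeric(160))
  # collinear atoms around the centre: sine channel vanishes
  lin <- rbind(c(0, 0, 0), c(0, 0, 1.5), c(0, 0, -1.5))
  expect_equal(a3Profile(lin, matrix(1, 3, 3) - diag(3), 1, "sin", g),
               numeric(160), tolerance = 1e-12)
  # cubic scaling in the weights
  expect_equal(a3Profile(co, 2 * om, 1, "cos", g),
               8 * a3Profile(co, om, 1, "cos", g), tolerance = 1e-9)
})

test_that("snapshot representations have length 3367 and match the oracle", {
  pair <- chiralPairFixture()
  cx <- pair$R
  rep <- snapshotRepresentation(cx)
  el <- elementsOf(cx)
  expect_equal(ncol(rep), 7 + 7 * 160 + 14 * 160)   # 3367
  expect_equal(nrow(rep), sum(el != "H"))
  expect_equal(rownames(rep), atomIds(cx)[el != "H"])
  # every block equals the naive per-channel computation
  w <- surrogateProvider()@fun(cx)
  g <- radialGrid()
  co <- coordsOf(cx)
  heavy <- which(el != "H")
  chn <- weightChannels()
  for (a in c(1L, length(heavy))) {
    i <- heavy[a]
    expect_equal(unname(rep[a, 1:7]), unname(w$a1[i, ]))
    for (c in seq_along(chn)) {
      om <- w$omega[[chn[c]]]
      expect_equal(rep[a, 7 + (c - 1) * 160 + 1:160],
                   oracleA2(co, om, i, g$centers), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(rep[a, 7 + 7 * 160 + (c - 1) * 160 + 1:160],
                   oracleA3(co, om, i, g$centers, "cos"), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(rep[a, 7 + 7 * 160 + (7 + c - 1) * 160 + 1:160],
                   oracleA3(co, om, i, g$centers, "sin"), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("representations are E(3)-invariant including reflections", {
  cx <- chiralPairFixture()$R
  base <- snapshotRepresentation(cx)
  co <- coordsOf(cx)
  rot <- snapshotRepresentation(cx, rotateCoords(co))
  expect_lt(max(abs(rot - base)), 1e-9)
  refl <- co; refl[, 1] <- -refl[, 1]
  expect_lt(max(abs(snapshotRepresentation(cx, refl) - base)), 1e-9)
})

test_that("hydrogen handling: never centres, neighbours by configuration", {
  cx <- chiralPairFixture()$R
  el <- elementsOf(cx)
  withH <- snapshotRepresentation(cx, includeHydrogens = TRUE)
  noH <- snapshotRepresentation(cx, includeHydrogens = FALSE)
  expect_equal(nrow(withH), sum(el != "H"))
  expect_false(isTRUE(all.equal(withH, noH)))
  # the hydrogen-free variant equals the oracle restricted to heavy atoms
  w <- surrogateProvider()@fun(cx)
  g <- radialGrid()
  i <- which(el != "H")[1]
  expect_equal(noH[1, 7 + 3 * 160 + 1:160],
               oracleA2(coordsOf(cx), w$omega$q, i, g$centers,
                        include = el != "H"),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("trajectory aggregation concatenates mean and population std", {
  cx <- achiralPairFixture()$R
  r1 <- snapshotRepresentation(cx)
  co2 <- coordsOf(cx)
  co2[1, ] <- co2[1, ] + c(0.05, -0.02, 0.01)
  r2 <- snapshotRepresentation(cx, co2)
  agg <- aggregateTrajectory(list(r1, r2))
  expect_equal(ncol(agg), 6734L)
  # two-point mean and population std, hand computed
  expect_equal(agg[, 1:3367], (r1 + r2) / 2, ignore_attr = TRUE)
  expect_equal(agg[, 3368:6734], abs(r1 - r2) / 2, ignore_attr = TRUE)
  # identical frames: zero std block
  same <- aggregateTrajectory(list(r1, r1, r1))
  expect_true(all(same[, 3368:6734] == 0))
  # frame order irrelevant
  expect_equal(aggregateTrajectory(list(r2, r1)), agg)
  expect_error(aggregateTrajectory(list(r1)), "2 frames")
  # static A1 integer fields have zero std even with moving frames
  expect_true(all(agg[, 3368:3370] == 0))
})

test_that("featurizeFrames streams to the same result as explicit aggregation", {
  pair <- achiralPairFixture()
  fs <- jitterEnsemble(pair$R, nFrames = 4L, amplitude = 0.04, seed = 2L)
  tr <- featurizeFrames(fs)
  expect_s4_class(tr, "TrajectoryRep")
  expect_equal(frameCount(tr), 4L)
  reps <- lapply(fs@frames, function(f) snapshotRepresentation(pair$R, f))
  expect_equal(tr@rep, aggregateTrajectory(reps), tolerance = 1e-12)
})

test_that("unbounded long-range channels ignore the cutoff for q and p only", {
  # the far atom sits just beyond the 8 Angstrom cutoff, where its Gaussian
  # still reaches the last grid bins once the cutoff is lifted
  cx <- saltComplex(
    molecule3d(c("C", "N"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
               role = "substrate"),
    molecule3d(c("O", "C"), rbind(c(0, 0, 3.2), c(0, 0, 8.2)),
               role = "resolving_agent"))
  bounded <- snapshotRepresentation(cx)
  unbounded <- snapshotRepresentation(cx, longRangeUnbounded = TRUE)
  g <- radialGrid()
  nb <- 160L
  qA2 <- 7 + 3 * nb + seq_len(nb)
  epsA2 <- 7 + 0 * nb + seq_len(nb)
  # the q channel picks up the atom beyond the cutoff, matching the oracle
  expect_gt(max(abs(bounded[1, qA2] - unbounded[1, qA2])), 1e-6)
  w <- surrogateProvider()@fun(cx)
  expect_equal(unbounded[1, qA2],
               oracleA2(coordsOf(cx), w$omega$q, 1, g$centers, cutoff = Inf),
               tolerance = 1e-10, ignore_attr = TRUE)
  # the far atom also enters the three-body q term as a partner atom
  qA3c <- 7 + 7 * nb + 3 * nb + seq_len(nb)
  # small charge products make the added three-body terms tiny but real
  expect_gt(max(abs(bounded[1, qA3c] - unbounded[1, qA3c])), 1e-9)
  expect_equal(unbounded[1, qA3c],
               oracleA3(coordsOf(cx), w$omega$q, 1, g$centers, "cos",
                        cutoff = Inf),
               tolerance = 1e-10, ignore_attr = TRUE)
  # ...while the overlap channels still honour the cutoff
  expect_identical(bounded[, epsA2], unbounded[, epsA2])
  # with everything inside the cutoff the flag changes nothing
  near <- chiralPairFixture()$R
  expect_identical(snapshotRepresentation(near),
                   snapshotRepresentation(near, longRangeUnbounded = TRUE))
})
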