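# Synthetic test inputs: toy chiral complexes with exact mirror control,
# jittered conformer ensembles standing in for MD trajectories, and labelled
# screening datasets with a planted, recoverable signal in compressed-diff
# space. The jitter sampler is a geometric stand-in: the MD protocol it
# emulates is recorded verbatim in [trajectoryProtocol()] and a real MD
# backend can be slotted in through the same FrameSet interface.

#' The emulated molecular-dynamics sampling protocol (metadata)
#'
#' Stored verbatim so the jitter sampler can record which physical protocol
#' it stands in for: 2 Angstrom initial closest-contact separation, a
#' restorative square-well keeping the molecules together, warming to 500 K
#' over 2.5 ps at a 0.25 fs time step, Langevin-thermostatted sampling every
#' 5 ps at 0.5 fs, 200 snapshots per pair.
#'
#' @return a list of protocol constants
#' @export
trajectoryProtocol <- function() {
  list(initial_separation = 2.0, restraint = "square-well",
       warm_T = 500, warm_time_ps = 2.5, warm_dt_fs = 0.25,
       sample_every_ps = 5, sample_dt_fs = 0.5,
       thermostat = "Langevin", n_snapshots = 200L)
}

# tetrahedral unit directions around the stereocentre
.tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

# substituent fragment templates: element, parent atom index within the
# fragment (0 = attachment bond towards the stereocentre), bond length to
# parent, azimuthal placement angle (degrees)
.fragDefs <- list(
  H     = data.frame(el = "H", parent = 0, blen = NA, phi = NA),
  F     = data.frame(el = "F", parent = 0, blen = NA, phi = NA),
  Cl    = data.frame(el = "Cl", parent = 0, blen = NA, phi = NA),
  Br    = data.frame(el = "Br", parent = 0, blen = NA, phi = NA),
  OH    = data.frame(el = c("O", "H"), parent = c(0, 1), blen = c(NA, 0.97),
                     phi = c(NA, 0)),
  SH    = data.frame(el = c("S", "H"), parent = c(0, 1), blen = c(NA, 1.34),
                     phi = c(NA, 0)),
  NH2   = data.frame(el = c("N", "H", "H"), parent = c(0, 1, 1),
                     blen = c(NA, 1.01, 1.01), phi = c(NA, 0, 120)),
  CH3   = data.frame(el = c("C", "H", "H", "H"), parent = c(0, 1, 1, 1),
                     blen = c(NA, 1.09, 1.09, 1.09), phi = c(NA, 0, 120, 240)),
  CH2OH = data.frame(el = c("C", "H", "H", "O", "H"),
                     parent = c(0, 1, 1, 1, 4),
                     blen = c(NA, 1.09, 1.09, 1.43, 0.97),
                     phi = c(NA, 120, 240, 0, 0)),
  COOH  = data.frame(el = c("C", "O", "O", "H"), parent = c(0, 1, 1, 3),
                     blen = c(NA, 1.21, 1.36, 0.97), phi = c(NA, 90, 210, 0)))

#' Substituent fragments available to the toy-molecule builder
#' @return character vector of fragment names
#' @export
fragmentLibrary <- function() names(.fragDefs)

covBond <- function(a, b) {
  pt <- ptableLookup(c(a, b), "bond length")
  sum(pt$rcov)
}

orthoBasis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# direction of a child bond: tetrahedral angle (109.47 deg) away from the
# bond back to the parent, i.e. 70.53 deg from the incoming direction,
# azimuth phi around it
branchDir <- function(incoming, phi) {
  d <- incoming / sqrt(sum(incoming^2))
  b <- orthoBasis(d)
  ct <- cos(70.53 * pi / 180); st <- sin(70.53 * pi / 180)
  a <- phi * pi / 180
  ct * d + st * (cos(a) * b$e1 + sin(a) * b$e2)
}

placeFragment <- function(fragName, centerPos, dir, centerEl, phiOffset = 0) {
  def <- .fragDefs[[fragName]]
  n <- nrow(def)
  pos <- matrix(0, n, 3)
  pos[1, ] <- centerPos + covBond(centerEl, def$el[1]) * dir
  if (n > 1) {
    for (k in 2:n) {
      p <- def$parent[k]
      incoming <- pos[p, ] - (if (p == 1) centerPos else pos[def$parent[p], ])
      pos[k, ] <- pos[p, ] + def$blen[k] *
        branchDir(incoming, def$phi[k] + phiOffset)
    }
  }
  list(elements = def$el, coords = pos)
}

#' Build a toy tetrahedral molecule from four substituent fragments
#'
#' A stereocentre (default carbon) at the origin with the four fragments on
#' tetrahedral directions. Four pairwise-distinct fragments guarantee a
#' chiral molecule.
#'
#' @param fragments character vector of four names from [fragmentLibrary()]
#' @param centerEl stereocentre element
#' @param role `"substrate"` or `"resolving_agent"`
#' @param idPrefix atom-id prefix
#' @param phiOffset global azimuthal dither (degrees), used for steric retries
#' @return a [Molecule3D-class]
#' @export
buildToyMolecule <- function(fragments, centerEl = "C", role = "substrate",
                             idPrefix = NULL, phiOffset = 0) {
  stopifnot(length(fragments) == 4L, all(fragments %in% fragmentLibrary()))
  el <- centerEl
  co <- matrix(0, 1, 3)
  for (i in 1:4) {
    fr <- placeFragment(fragments[i], c(0, 0, 0), .tetra[i, ], centerEl,
                        phiOffset)
    el <- c(el, fr$elements)
    co <- rbind(co, fr$coords)
  }
  if (is.null(idPrefix)) idPrefix <- if (role == "substrate") "sub" else "agt"
  molecule3d(el, co, role = role,
             atomIds = paste0(idPrefix, "_", seq_along(el)))
}

#' Mirror a molecule through the x = 0 plane
#' @param mol a [Molecule3D-class]
#' @return the mirrored molecule (an exact involution)
#' @export
mirrorMolecule <- function(mol) {
  co <- mol@coords
  co[, 1] <- -co[, 1]
  molecule3d(mol@elements, co, role = mol@role, atomIds = mol@atomIds)
}

# planar (x = 0) formic-acid-like resolving agent: invariant under the
# x -> -x mirror by construction, i.e. achiral as placed
planarAgentGeometry <- function() {
  molecule3d(c("C", "O", "O", "H", "H"),
             rbind(c(0, 0, 0), c(0, 1.06, 0.57), c(0, -1.12, 0.42),
                   c(0, 0.12, -1.02), c(0, -1.64, 1.17)),
             role = "resolving_agent",
             atomIds = paste0("agt_", 1:5))
}

minInterDist <- function(subCo, agtCo) {
  min(sqrt(outer(rowSums(subCo^2), rowSums(agtCo^2), "+") -
             2 * tcrossprod(subCo, agtCo)))
}

# translate the agent along z until the closest substrate-agent contact sits
# at `sep`; purely a function of interatomic distances, so mirrored
# geometries re-pose to bitwise-identical offsets
poseAgent <- function(subCo, agtCo, sep = 2.0) {
  shift <- max(subCo[, 3]) - min(agtCo[, 3]) + sep + 2
  agt <- agtCo
  agt[, 3] <- agt[, 3] + shift
  for (it in 1:40) {
    d <- minInterDist(subCo, agt)
    delta <- d - sep
    if (abs(delta) < 1e-9) break
    agt[, 3] <- agt[, 3] - delta
  }
  agt
}

minSelfDist <- function(co) {
  if (nrow(co) < 2) return(Inf)
  min(stats::dist(co))
}

#' Construct the two diastereomeric complexes of a toy racemate
#'
#' The S substrate is the exact mirror (x to -x) of the R substrate; both
#' are re-posed against the same agent geometry at a 2 Angstrom closest
#' contact. Atom ordering is identical across the pair. With the planar
#' achiral agent (`agentSpec = "achiral_planar"`) the two complexes are
#' exact mirror images; with a chiral agent they are genuine diastereomers.
#'
#' @param fragments four distinct substituent fragments for the substrate
#' @param agentSpec four fragments for a chiral tetrahedral agent, or the
#'   string `"achiral_planar"`
#' @param separation closest-contact pose distance, Angstrom
#' @param minClearance steric limit: retry/error below this intramolecular
#'   distance
#' @return list with elements `R` and `S`, both [SaltComplex-class]
#' @export
makeChiralComplex <- function(fragments, agentSpec = "achiral_planar",
                              separation = 2.0, minClearance = 0.8) {
  if (anyDuplicated(fragments))
    stop("the four substituent fragments must be pairwise distinct ",
         "(chirality guarantee)", call. = FALSE)
  buildOk <- function(builder) {
    for (off in c(0, 20, 40, 60, 80)) {
      m <- builder(off)
      if (minSelfDist(m@coords) >= minClearance) return(m)
    }
    stop("substituent steric collision below ", minClearance,
         " Angstrom after retries", call. = FALSE)
  }
  subR <- buildOk(function(off) buildToyMolecule(fragments, role = "substrate",
                                                 phiOffset = off))
  agent <- if (identical(agentSpec, "achiral_planar")) {
    planarAgentGeometry()
  } else {
    if (anyDuplicated(agentSpec))
      stop("chiral agent fragments must be pairwise distinct", call. = FALSE)
    buildOk(function(off) buildToyMolecule(agentSpec, role = "resolving_agent",
                                           phiOffset = off))
  }
  subS <- mirrorMolecule(subR)
  mk <- function(sub, hand) {
    agtPosed <- molecule3d(agent@elements,
                           poseAgent(sub@coords, agent@coords, separation),
                           role = "resolving_agent", atomIds = agent@atomIds)
    saltComplex(sub, agtPosed, handedness = hand)
  }
  list(R = mk(subR, "R"), S = mk(subS, "S"))
}

rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle); C <- 1 - c0
  rbind(c(c0 + a[1]^2 * C, a[1] * a[2] * C - a[3] * s0, a[1] * a[3] * C + a[2] * s0),
        c(a[2] * a[1] * C + a[3] * s0, c0 + a[2]^2 * C, a[2] * a[3] * C - a[1] * s0),
        c(a[3] * a[1] * C - a[2] * s0, a[3] * a[2] * C + a[1] * s0, c0 + a[3]^2 * C))
}

# one frame's raw perturbation draws (shared between mirror-paired complexes)
drawFrameNoise <- function(nSub, nAgt, amplitude, maxRot, band) {
  list(subDisp = matrix(stats::rnorm(nSub * 3, sd = amplitude), nSub, 3),
       agtDisp = matrix(stats::rnorm(nAgt * 3, sd = amplitude), nAgt, 3),
       axis = stats::rnorm(3),
       angle = stats::runif(1, -maxRot, maxRot),
       target = stats::runif(1, band[1], band[2]))
}

applyFrameNoise <- function(complex, nz, mirror = FALSE) {
  subCo <- complex@substrate@coords
  agtCo <- complex@agent@coords
  M <- function(x) { if (mirror) x[, 1] <- -x[, 1]; x }
  subCo <- subCo + M(nz$subDisp)
  ctr <- colMeans(agtCo)
  # conjugating a rotation by a reflection flips the axis x-component AND
  # the sense of rotation; this keeps mirror-paired frames exact mirrors
  axis <- as.numeric(M(matrix(nz$axis, 1)))
  Q <- rotationMatrix(axis, if (mirror) -nz$angle else nz$angle)
  agtCo <- sweep(tcrossprod(sweep(agtCo, 2, ctr), Q), 2, ctr, "+")
  agtCo <- agtCo + M(nz$agtDisp)
  agtCo <- poseAgent(subCo, agtCo, nz$target)
  rbind(subCo, agtCo)
}

#' Jittered conformer ensemble for a single complex
#'
#' Frames are the base coordinates plus seeded Gaussian displacements, with
#' a random rigid re-orientation of the agent followed by a re-posing
#' translation that keeps the closest intermolecular contact within the
#' configured distance band (emulating the square-well contact restraint of
#' the recorded protocol).
#'
#' @param complex a [SaltComplex-class]
#' @param nFrames number of frames (the emulated protocol samples 200)
#' @param amplitude per-atom Gaussian displacement, Angstrom
#' @param seed RNG seed
#' @param band closest-contact band (Angstrom) enforced per frame
#' @param maxRot maximum agent re-orientation angle (radians)
#' @return a [FrameSet-class]
#' @export
jitterEnsemble <- function(complex, nFrames = 200L, amplitude = 0.05,
                           seed = 1L, band = c(1.8, 2.6), maxRot = 0.3) {
  stopifnot(amplitude >= 0, nFrames >= 2L)
  nS <- nAtoms(complex@substrate); nA <- nAtoms(complex@agent)
  frames <- withSeed(seed, lapply(seq_len(nFrames), function(f) {
    nz <- drawFrameNoise(nS, nA, amplitude, if (amplitude > 0) maxRot else 0,
                         band)
    if (amplitude == 0) {
      nz$angle <- 0
      nz$target <- minInterDist(complex@substrate@coords, complex@agent@coords)
    }
    applyFrameNoise(complex, nz)
  }))
  new("FrameSet", complexTemplate = complex, frames = frames)
}

#' Mirror-paired conformer ensembles for a diastereomer pair
#'
#' Draws one set of perturbations per frame and applies it to the R complex
#' directly and to the S complex mirrored (displacements reflected, the
#' agent rotation conjugated by the reflection). When the agent is achiral
#' and placed in the mirror plane, every S frame is then the exact mirror
#' image of the matching R frame, so the pair's diff stream vanishes
#' identically; a chiral agent breaks the symmetry.
#'
#' @param pair list with `R` and `S` complexes from [makeChiralComplex()]
#' @inheritParams jitterEnsemble
#' @return list with `R` and `S` [FrameSet-class] objects
#' @export
makePairFrames <- function(pair, nFrames = 200L, amplitude = 0.05, seed = 1L,
                           band = c(1.8, 2.6), maxRot = 0.3) {
  nS <- nAtoms(pair$R@substrate); nA <- nAtoms(pair$R@agent)
  noise <- withSeed(seed, lapply(seq_len(nFrames), function(f)
    drawFrameNoise(nS, nA, amplitude, if (amplitude > 0) maxRot else 0, band)))
  fix0 <- function(cx, nz) {
    if (amplitude == 0) {
      nz$angle <- 0
      nz$target <- minInterDist(cx@substrate@coords, cx@agent@coords)
    }
    nz
  }
  framesR <- lapply(noise, function(nz) applyFrameNoise(pair$R, fix0(pair$R, nz)))
  framesS <- lapply(noise, function(nz) applyFrameNoise(pair$S, fix0(pair$S, nz),
                                                        mirror = TRUE))
  list(R = new("FrameSet", complexTemplate = pair$R, frames = framesR),
       S = new("FrameSet", complexTemplate = pair$S, frames = framesS))
}

sampleFragments <- function(library, mustHave = NULL) {
  rest <- sample(setdiff(library, mustHave), 4 - length(mustHave))
  sample(c(mustHave, rest))
}

#' Generate a synthetic resolution-screening dataset with a planted signal
#'
#' Builds a full racemate x agent x solvent experiment grid over toy chiral
#' complexes, featurizes mirror-paired jitter ensembles, and plants a
#' logistic success signal in the compressed-diff space: the hit probability
#' of a pair is `plogis(slope * proj + solventCoef * solvProj + intercept)`,
#' where `proj` is the standardised projection of the pair's mean diff-stream
#' vector (under an internal PCA compressor) onto a random unit direction
#' and the intercept is calibrated so the mean hit probability equals
#' `baseRate`. Labels get `labelNoise` random flips; figures of merit are
#' then drawn consistently with the final label (hits satisfy
#' `m_frac > 0.2` and `ee > 0.25`, non-hits violate at least one threshold,
#' and every record respects the maximum-possible-e.e. band).
#'
#' @param nRacemates,nAgents,nSolvents grid dimensions (`nRacemates >= 5`)
#' @param baseRate target hit rate after label noise, in (labelNoise, 0.5);
#'   the intercept calibration accounts for the noise so the realised rate
#'   matches this value in expectation
#' @param slope planted logistic slope; 0 gives a constant-probability null
#' @param solventCoef logistic weight of the solvent projection
#' @param labelNoise probability of flipping a drawn label; keep small
#'   relative to `baseRate` (at the defaults ~15 percent of hits are
#'   noise-born), since the flips dominate the hit class once the rates are
#'   comparable
#' @param lowMassShare share of non-hits failing by low mass fraction
#'   (m_frac < 0.2); the complement fails by low ee but stays in the
#'   low-noise subset. The default 0.64 puts the low-noise subset's hit rate
#'   near 8 percent when the overall rate is 3 percent, mirroring the class
#'   balance of historical screening data
#' @param framesPerPair jitter frames per complex
#' @param amplitude jitter amplitude, Angstrom
#' @param solventDim solvent descriptor length
#' @param seed master seed; everything is reproducible from it
#' @param provider weight provider for featurization
#' @return list with `records` (labelled data.frame), `complexes`, `frames`,
#'   `reps` (per pair id, `R`/`S` [TrajectoryRep-class]), `solvents`
#'   (descriptor table), and `signal` (true direction, intercept,
#'   per-pair projections, internal compressor)
#' @export
generateDataset <- function(nRacemates = 30L, nAgents = 20L, nSolvents = 3L,
                            baseRate = 0.03, slope = 4, solventCoef = 0.5,
                            labelNoise = 0.005, lowMassShare = 0.64,
                            framesPerPair = 16L, amplitude = 0.08,
                            solventDim = 8L, seed = 1L,
                            provider = surrogateProvider()) {
  stopifnot(nRacemates >= 5L, baseRate > labelNoise, baseRate < 0.5)
  lib <- c("H", "F", "Cl", "Br", "CH3", "OH", "NH2", "SH")
  withSeed(seed, {
    racSpecs <- lapply(seq_len(nRacemates), function(i)
      sampleFragments(lib, mustHave = "NH2"))
    agtSpecs <- lapply(seq_len(nAgents), function(i)
      sampleFragments(c(lib, "COOH"), mustHave = "COOH"))
    solvents <- matrix(stats::rnorm(nSolvents * solventDim), nSolvents)
    solvents <- as.data.frame(solvents)
    names(solvents) <- paste0("desc_", seq_len(solventDim))
    rownames(solvents) <- paste0("solv_", seq_len(nSolvents))
    pairSeeds <- sample.int(2^30, nRacemates * nAgents)
    w20 <- stats::rnorm(20)
    w20 <- w20 / sqrt(sum(w20^2))
    u <- stats::rnorm(solventDim)
  })

  pairIds <- character(0)
  complexes <- list(); frames <- list(); reps <- list()
  k <- 0L
  for (r in seq_len(nRacemates)) {
    for (a in seq_len(nAgents)) {
      k <- k + 1L
      pid <- sprintf("rac%02d_agt%02d", r, a)
      pairIds <- c(pairIds, pid)
      cx <- makeChiralComplex(racSpecs[[r]], agtSpecs[[a]])
      fr <- makePairFrames(cx, nFrames = framesPerPair, amplitude = amplitude,
                           seed = pairSeeds[k])
      complexes[[pid]] <- cx
      frames[[pid]] <- fr
      reps[[pid]] <- list(R = featurizeFrames(fr$R, provider),
                          S = featurizeFrames(fr$S, provider))
    }
  }

  # internal compressor for the planted signal (PCA over a row subsample)
  allRows <- do.call(rbind, lapply(reps, function(p) rbind(p$R@rep, p$S@rep)))
  sub <- withSeed(seed + 1L, sample.int(nrow(allRows), min(1500L, nrow(allRows))))
  comp <- trainCompressor(allRows[sub, , drop = FALSE], kind = "pca",
                          seed = seed + 2L)
  x <- t(vapply(pairIds, function(pid) {
    pt <- buildPair(reps[[pid]]$R, reps[[pid]]$S, comp)
    colMeans(pt@diffStream)
  }, numeric(20)))
  proj <- as.numeric(x %*% w20)
  psd <- stats::sd(proj)
  proj <- if (psd > 0) (proj - mean(proj)) / psd else proj * 0
  sprojRaw <- as.numeric(as.matrix(solvents) %*% u)
  ssd <- stats::sd(sprojRaw)
  sproj <- if (nSolvents > 1 && ssd > 0) (sprojRaw - mean(sprojRaw)) / ssd
           else sprojRaw * 0

  grid <- expand.grid(pair = seq_along(pairIds), solv = seq_len(nSolvents))
  lin <- slope * proj[grid$pair] + solventCoef * sproj[grid$solv]
  # calibrate the intercept on the post-noise rate:
  # P(hit) = p (1 - eps) + (1 - p) eps
  targetP <- (baseRate - labelNoise) / (1 - 2 * labelNoise)
  intercept <- stats::uniroot(function(b) mean(stats::plogis(lin + b)) - targetP,
                              c(-50, 50), tol = 1e-10)$root
  p <- stats::plogis(lin + intercept)
  pEff <- p * (1 - labelNoise) + (1 - p) * labelNoise

  withSeed(seed + 3L, {
    hit <- stats::runif(length(p)) < p
    flip <- stats::runif(length(p)) < labelNoise
    hit <- xor(hit, flip)
    n <- length(hit)
    m_frac <- numeric(n); ee <- numeric(n)
    isHit <- which(hit); notHit <- which(!hit)
    m_frac[isHit] <- stats::runif(length(isHit), 0.22, 0.5)
    ee[isHit] <- stats::runif(length(isHit), 0.30, 0.95)
    lowMass <- stats::runif(length(notHit)) < lowMassShare
    m_frac[notHit[lowMass]] <- stats::runif(sum(lowMass), 0, 0.18)
    ee[notHit[lowMass]] <- stats::runif(sum(lowMass), 0, 0.9)
    m_frac[notHit[!lowMass]] <- stats::runif(sum(!lowMass), 0.2, 0.7)
    ee[notHit[!lowMass]] <- stats::runif(sum(!lowMass), 0, 0.24)
    fullDiss <- stats::runif(n) < ifelse(hit, 0.7, 0.3)
    records <- data.frame(
      racemate_id = sprintf("rac%02d", ((grid$pair - 1) %/% nAgents) + 1),
      agent_id = sprintf("agt%02d", ((grid$pair - 1) %% nAgents) + 1),
      pair_id = pairIds[grid$pair],
      solvent_ids = I(as.list(rownames(solvents)[grid$solv])),
      solvent_fractions = I(rep(list(1), n)),
      m_frac = m_frac, ee = ee, full_dissolution = fullDiss,
      hit_prob = pEff, stringsAsFactors = FALSE)
  })
  records <- labelRecords(records)

  list(records = records, complexes = complexes, frames = frames, reps = reps,
       solvents = solvents,
       signal = list(w = w20, slope = slope, intercept = intercept,
                     solventCoef = solventCoef, proj = proj, sproj = sproj,
                     compressor = comp))
}

#' Build per-record pair tensors for a generated dataset
#'
#' Encodes each pair's trajectory representations with the supplied
#' compressor (train it on training-split atoms only) and attaches the
#' solvent descriptor vector of each record.
#'
#' @param dataset output of [generateDataset()]
#' @param compressor a trained [Compressor-class]
#' @param records subset of `dataset$records` to build (default all)
#' @return list of [PairTensors-class], aligned with `records` rows
#' @export
preparePairs <- function(dataset, compressor, records = dataset$records) {
  base <- lapply(unique(records$pair_id), function(pid) {
    buildPair(dataset$reps[[pid]]$R, dataset$reps[[pid]]$S, compressor)
  })
  names(base) <- unique(records$pair_id)
  lapply(seq_len(nrow(records)), function(i) {
    sv <- solventVector(records$solvent_ids[[i]],
                        records$solvent_fractions[[i]], dataset$solvents)
    attachSolvent(base[[records$pair_id[i]]], sv)
  })
}

#' Gather the per-atom representation rows of a record subset
#'
#' Convenience for training fold compressors on training atoms only.
#'
#' @param dataset output of [generateDataset()]
#' @param records record subset whose pairs contribute rows
#' @param nmax optional row subsample cap (seeded)
#' @param seed subsample seed
#' @return numeric matrix of per-atom trajectory representations
#' @export
gatherRepRows <- function(dataset, records, nmax = Inf, seed = 1L) {
  m <- do.call(rbind, lapply(unique(records$pair_id), function(pid)
    rbind(dataset$reps[[pid]]$R@rep, dataset$reps[[pid]]$S@rep)))
  if (nrow(m) > nmax)
    m <- m[withSeed(seed, sample.int(nrow(m), nmax)), , drop = FALSE]
  m
}
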