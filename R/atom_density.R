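# Weighted atom-density representations (2- and 3-body radial profiles on a
# fixed grid) and their aggregation over conformer ensembles.

#' The radial evaluation grid
#'
#' 160 evenly spaced radii from 0.7 to 8 Angstrom, inclusive of both
#' endpoints. Profiles are evaluated pointwise at the bin centres.
#'
#' @param r_min,r_max grid range in Angstrom
#' @param n_bins number of bins
#' @return list with `centers`, `r_min`, `r_max`, `n_bins`
#' @export
radialGrid <- function(r_min = 0.7, r_max = 8.0, n_bins = 160L) {
  stopifnot(r_max > r_min, n_bins >= 2L)
  list(centers = seq(r_min, r_max, length.out = n_bins),
       r_min = r_min, r_max = r_max, n_bins = as.integer(n_bins))
}

#' The radial Gaussian placed at a neighbour atom
#'
#' `G_ij(r) = exp(-(d_ij - r)^2 / (2 sigma^2)) / (sigma sqrt(2 pi))`, a
#' normal density in r centred at the interatomic distance; it integrates to
#' one over the real line. The default width is 0.0825 Angstrom.
#'
#' @param d interatomic distance(s), Angstrom (> 0)
#' @param r radius / radii at which to evaluate, Angstrom
#' @param sigma Gaussian width, Angstrom
#' @return density value(s), 1/Angstrom
#' @export
gaussianDensity <- function(d, r, sigma = 0.0825) {
  stopifnot(all(d > 0), sigma > 0)
  exp(-(d - r)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

neighbourInfo <- function(coords, i, cutoff, include = NULL) {
  dvec <- sqrt(rowSums((coords - matrix(coords[i, ], nrow(coords), 3,
                                        byrow = TRUE))^2))
  keep <- seq_len(nrow(coords)) != i & dvec <= cutoff & dvec > 0
  if (!is.null(include)) keep <- keep & include
  list(idx = which(keep), d = dvec[keep])
}

#' Two-body weighted density profile of one atom
#'
#' Sum over neighbours j within the cutoff of `w_ij * G_ij(r)`, evaluated at
#' every grid centre.
#'
#' @param coords N x 3 snapshot coordinates (Angstrom)
#' @param omega N x N weight matrix for one channel
#' @param i central atom index
#' @param grid a [radialGrid()]
#' @param cutoff neighbour cutoff, Angstrom
#' @param sigma Gaussian width, Angstrom
#' @param include optional logical vector marking admissible neighbours
#' @return numeric vector of length `grid$n_bins`
#' @export
a2Profile <- function(coords, omega, i, grid = radialGrid(), cutoff = 8.0,
                      sigma = 0.0825, include = NULL) {
  nb <- neighbourInfo(coords, i, cutoff, include)
  if (!length(nb$idx)) return(numeric(grid$n_bins))
  g <- outer(nb$d, grid$centers, function(d, r) gaussianDensity(d, r, sigma))
  as.numeric(crossprod(g, omega[nb$idx, i]))
}

#' Three-body weighted density profile of one atom
#'
#' Sum over ordered neighbour pairs (j, k), j != k, both within the cutoff,
#' of `w_ij w_ik w_jk G_ij(r) phi(theta_ijk)`, where `theta_ijk` is the angle
#' at the central atom i between the bonds i->j and i->k and `phi` is sine or
#' cosine. Excluding j = k is required (the angle of an atom with itself is
#' degenerate); the remaining sum is symmetric over unordered pairs, giving
#' each pair weight 2.
#'
#' @inheritParams a2Profile
#' @param angleFn `"cos"` or `"sin"`
#' @return numeric vector of length `grid$n_bins`
#' @export
a3Profile <- function(coords, omega, i, angleFn = c("cos", "sin"),
                      grid = radialGrid(), cutoff = 8.0, sigma = 0.0825,
                      include = NULL) {
  angleFn <- match.arg(angleFn)
  nb <- neighbourInfo(coords, i, cutoff, include)
  m <- length(nb$idx)
  if (m < 2L) return(numeric(grid$n_bins))
  u <- (coords[nb$idx, , drop = FALSE] -
          matrix(coords[i, ], m, 3, byrow = TRUE)) / nb$d
  ct <- pmin(pmax(tcrossprod(u), -1), 1)   # matrix first: keeps dim
  ang <- if (angleFn == "cos") ct else sqrt(1 - ct^2)
  wik <- omega[nb$idx, i]
  wjk <- omega[nb$idx, nb$idx, drop = FALSE]
  inner <- (ang * wjk) %*% wik - diag(ang) * diag(wjk) * wik  # drop k = j
  coef <- omega[nb$idx, i] * as.numeric(inner)
  g <- outer(nb$d, grid$centers, function(d, r) gaussianDensity(d, r, sigma))
  as.numeric(crossprod(g, coef))
}

#' Full per-atom representation of one snapshot
#'
#' For every non-hydrogen atom the vector `A1 || A2 || A3` is assembled: 7
#' identity features, 7 weighting channels x 160 bins of two-body profiles,
#' and 14 (7 channels x cos/sin) x 160 bins of three-body profiles - 3367
#' values per atom. Hydrogens are never centres; by default they do count as
#' neighbours (they carry charge in the q channel), controlled by
#' `includeHydrogens`.
#'
#' @param complex a [SaltComplex-class]
#' @param coords snapshot coordinates (defaults to the complex geometry)
#' @param provider a [WeightProvider-class]
#' @param grid a [radialGrid()]
#' @param cutoff neighbour cutoff, Angstrom
#' @param sigma Gaussian width, Angstrom
#' @param includeHydrogens include hydrogens as neighbours?
#' @param longRangeUnbounded drop the cutoff for the distance-independent
#'   charge and population channels (`q`, `p*`), which carry the long-range
#'   information; the overlap channels always honour the cutoff
#' @return numeric matrix, heavy atoms x 3367, rownames = heavy-atom ids
#' @export
snapshotRepresentation <- function(complex, coords = NULL,
                                   provider = surrogateProvider(),
                                   grid = radialGrid(), cutoff = 8.0,
                                   sigma = 0.0825, includeHydrogens = TRUE,
                                   longRangeUnbounded = FALSE) {
  if (is.null(coords)) coords <- coordsOf(complex)
  el <- elementsOf(complex)
  heavy <- el != "H"
  w <- provider@fun(complex, coords)
  rep <- snapshotRepCpp(coords, unname(w$omega[weightChannels()]), w$a1,
                        heavy, grid$centers, sigma, cutoff, includeHydrogens)
  if (longRangeUnbounded) {
    # recompute the q/p channel blocks with no distance cutoff and splice
    # them in (channels never mix, so block replacement is exact)
    unb <- snapshotRepCpp(coords, unname(w$omega[weightChannels()]), w$a1,
                          heavy, grid$centers, sigma, .Machine$double.xmax,
                          includeHydrogens)
    nb <- grid$n_bins
    lr <- which(weightChannels() %in% c("q", "p_sigma", "p_pi", "p_delta"))
    for (c in lr) {
      a2 <- 7 + (c - 1) * nb + seq_len(nb)
      a3c <- 7 + 7 * nb + (c - 1) * nb + seq_len(nb)
      a3s <- 7 + 7 * nb + (7 + c - 1) * nb + seq_len(nb)
      rep[, c(a2, a3c, a3s)] <- unb[, c(a2, a3c, a3s)]
    }
  }
  rownames(rep) <- atomIds(complex)[heavy]
  rep
}

#' Aggregate snapshot representations into a trajectory representation
#'
#' Concatenates the per-atom mean and standard deviation (population
#' convention, i.e. dividing by the number of frames) of the snapshot
#' vectors: 2 x 3367 = 6734 values per atom. The static A1 integer fields
#' have zero standard deviation by construction.
#'
#' @param frameReps list (length >= 2) of heavy-atoms x 3367 matrices
#' @return numeric matrix, heavy atoms x 6734
#' @export
aggregateTrajectory <- function(frameReps) {
  nf <- length(frameReps)
  if (nf < 2L) stop("at least 2 frames required (std undefined)", call. = FALSE)
  # accumulate relative to the first frame: entries that never move (static
  # A1 fields, identical frames) get an exactly zero std
  ref <- frameReps[[1]]
  s <- 0; s2 <- 0
  for (x in frameReps) {
    d <- x - ref
    s <- s + d
    s2 <- s2 + d * d
  }
  mu <- ref + s / nf
  v <- pmax(s2 / nf - (s / nf)^2, 0)
  out <- cbind(mu, sqrt(v))
  rownames(out) <- rownames(frameReps[[1]])
  out
}

#' Featurize a conformer ensemble into a TrajectoryRep
#'
#' Runs [snapshotRepresentation()] on every frame and aggregates with
#' [aggregateTrajectory()] in a streaming fashion.
#'
#' @param frameSet a [FrameSet-class]
#' @inheritParams snapshotRepresentation
#' @return a [TrajectoryRep-class]
#' @export
featurizeFrames <- function(frameSet, provider = surrogateProvider(),
                            grid = radialGrid(), cutoff = 8.0, sigma = 0.0825,
                            includeHydrogens = TRUE) {
  cx <- frameSet@complexTemplate
  nf <- frameCount(frameSet)
  ref <- NULL; s <- 0; s2 <- 0
  for (f in frameSet@frames) {
    r <- snapshotRepresentation(cx, f, provider, grid, cutoff, sigma,
                                includeHydrogens)
    if (is.null(ref)) ref <- r
    d <- r - ref
    s <- s + d
    s2 <- s2 + d * d
  }
  mu <- ref + s / nf
  v <- pmax(s2 / nf - (s / nf)^2, 0)
  rep <- cbind(mu, sqrt(v))
  new("TrajectoryRep", rep = rep, atomIds = rownames(mu),
      frameCount = as.integer(nf))
}
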