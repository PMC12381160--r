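# Per-atom identity features (A1) and pairwise weighting channels for the
# atom-density representation. The seven channels are
#   W = {eps_sigma, eps_pi, eps_delta, q, p_sigma, p_pi, p_delta}:
# orbital-overlap weights (symmetric, distance-decaying), the charge product
# q_ij = q_i * q_j, and orbital-population products. Providers are pluggable:
# the built-in surrogate derives everything from the geometry and a static
# periodic table; an adapter ingests externally computed semi-empirical
# output from a file.

#' Names of the seven weighting channels
#' @return character vector in canonical order
#' @export
weightChannels <- function() {
  c("eps_sigma", "eps_pi", "eps_delta", "q", "p_sigma", "p_pi", "p_delta")
}

#' Names of the seven per-atom identity (A1) features
#' @return character vector
#' @export
a1FeatureNames <- function() {
  c("nuclear_charge", "group", "period", "partial_charge",
    "pop_s", "pop_p", "pop_d")
}

# Electronegativity-equalisation charges: minimise
#   sum_i chi_i q_i + eta_i q_i^2 + sum_{i<j} J q_i q_j / d_ij
# subject to sum q_i = 0. Solved as a bordered linear system; the constraint
# makes the charges sum to zero to solver precision.
eeqCharges <- function(elements, coords, coupling = 1.0) {
  pt <- ptableLookup(elements, "surrogate charges")
  n <- length(elements)
  d <- as.matrix(stats::dist(coords))
  A <- coupling / pmax(d, 0.5)   # short-distance cap keeps the system well posed
  diag(A) <- 2 * pt$eta
  M <- rbind(cbind(A, 1), c(rep(1, n), 0))
  rhs <- c(-pt$chi, 0)
  sol <- solve(M, rhs)
  sol[seq_len(n)]
}

# Neutral valence-shell populations adjusted by the partial charge: electrons
# are removed from (or added to) the p shell where the element has p valence,
# otherwise the s shell; populations are floored at zero.
surrogatePopulations <- function(elements, q) {
  pt <- ptableLookup(elements, "surrogate populations")
  pop <- cbind(s = pt$val_s, p = pt$val_p, d = pt$val_d)
  hasP <- pt$val_p > 0
  pop[hasP, "p"] <- pop[hasP, "p"] - q[hasP]
  pop[!hasP, "s"] <- pop[!hasP, "s"] - q[!hasP]
  pop[pop < 0] <- 0
  pop
}

# sigma/pi/delta bonding capacities: the neutral valence s, p and d electron
# counts. The supported set has no d valence, so delta channels vanish.
surrogateCapacities <- function(elements) {
  pt <- ptableLookup(elements, "surrogate capacities")
  cbind(sigma = pt$val_s, pi = pt$val_p, delta = pt$val_d)
}

buildOmega <- function(q, pop, epsFun) {
  out <- list(
    eps_sigma = epsFun("sigma"),
    eps_pi    = epsFun("pi"),
    eps_delta = epsFun("delta"),
    q         = tcrossprod(q),
    p_sigma   = tcrossprod(pop[, "s"]),
    p_pi      = tcrossprod(pop[, "p"]),
    p_delta   = tcrossprod(pop[, "d"]))
  for (nm in names(out)) diag(out[[nm]]) <- 0
  out
}

#' Built-in surrogate electronic-weight provider
#'
#' A deterministic, geometry-only stand-in for a semi-empirical calculation:
#' partial charges from an electronegativity-equalisation scheme (summing to
#' zero over a neutral complex), orbital populations from neutral valence
#' configurations adjusted by the charge, and overlap channels
#' `eps* = s*_i s*_j exp(-(d_ij - r_cov,i - r_cov,j) / lambda)` with
#' per-element sigma/pi/delta capacities `s*` and decay length `lambda`
#' (default 0.5 Angstrom, the covalent-overlap scale). All channels depend
#' only on interatomic distances and scalar atom properties, hence are
#' invariant under rigid rotations, translations and reflections.
#'
#' @param lambda overlap decay length in Angstrom
#' @return a [WeightProvider-class]
#' @export
surrogateProvider <- function(lambda = 0.5) {
  fun <- function(complex, coords = NULL) {
    if (is.null(coords)) coords <- coordsOf(complex)
    el <- elementsOf(complex)
    pt <- ptableLookup(el, "surrogate provider")
    q <- eeqCharges(el, coords)
    pop <- surrogatePopulations(el, q)
    caps <- surrogateCapacities(el)
    d <- as.matrix(stats::dist(coords))
    rsum <- outer(pt$rcov, pt$rcov, "+")
    decay <- exp(-(d - rsum) / lambda)
    epsFun <- function(type) tcrossprod(caps[, type]) * decay
    a1 <- cbind(pt$z, pt$group, pt$period, q, pop)
    colnames(a1) <- a1FeatureNames()
    rownames(a1) <- atomIds(complex)
    list(a1 = a1, omega = buildOmega(q, pop, epsFun))
  }
  new("WeightProvider", name = "surrogate", fun = fun)
}

#' Compute the per-atom identity (A1) features of a complex
#'
#' Seven values per atom: nuclear charge, periodic group and period (static
#' periodic-table lookups), the partial charge, and the s/p/d orbital
#' populations (provider-dependent).
#'
#' @param complex a [SaltComplex-class]
#' @param provider a [WeightProvider-class]; defaults to the surrogate
#' @return numeric matrix, atoms x 7
#' @export
computeA1 <- function(complex, provider = surrogateProvider()) {
  provider@fun(complex)$a1
}

#' Evaluate one pairwise weighting channel for an atom pair
#'
#' @param channel one of [weightChannels()]
#' @param i,j atom indices in the complex (must differ)
#' @param complex a [SaltComplex-class]
#' @param provider a [WeightProvider-class]
#' @param coords optional coordinates overriding the complex geometry
#' @return scalar weight
#' @export
pairWeight <- function(channel, i, j, complex,
                       provider = surrogateProvider(), coords = NULL) {
  if (!channel %in% weightChannels())
    stop("unknown weighting channel: ", channel, call. = FALSE)
  if (i == j) stop("pair weights require i != j", call. = FALSE)
  w <- provider@fun(complex, coords)
  w$omega[[channel]][i, j]
}

#' Adapter for externally computed semi-empirical weights
#'
#' Reads a plain-text exchange file holding the per-atom charges and orbital
#' populations and the pairwise sigma/pi/delta overlap matrices that an
#' external converter extracts from a semi-empirical (e.g. PM7) run. The
#' library never executes the external code itself. Format: a `NATOMS n`
#' line, then blocks headed `ELEMENTS`, `CHARGES`, `POPULATIONS` (one `s p d`
#' row per atom) and `OVERLAP_SIGMA` / `OVERLAP_PI` / `OVERLAP_DELTA`
#' (whitespace-separated `i j value` triplets, 1-based, symmetrised on read),
#' terminated by `END`. Overlap values are taken as static properties of the
#' geometry the external run used and are applied to every frame.
#'
#' @param path exchange file path
#' @return a [WeightProvider-class]
#' @export
externalProviderAdapter <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  natLine <- grep("^NATOMS\\b", lines, value = TRUE)
  if (!length(natLine)) stop("parse error: missing NATOMS block", call. = FALSE)
  n <- as.integer(strsplit(natLine[1], "[[:space:]]+")[[1]][2])
  grabBlock <- function(name, nrows = NULL) {
    start <- match(name, lines)
    if (is.na(start)) stop("parse error: missing ", name, " block", call. = FALSE)
    stops <- which(grepl("^[A-Z_]+$", lines) | lines == "END")
    stop_at <- min(c(stops[stops > start], length(lines) + 1L))
    body <- if (stop_at - 1L < start + 1L) character(0)
            else lines[seq(start + 1L, stop_at - 1L)]
    if (!is.null(nrows) && length(body) < nrows)
      stop("parse error: truncated ", name, " block", call. = FALSE)
    body
  }
  el <- canonicalElement(unlist(strsplit(grabBlock("ELEMENTS"), "[[:space:]]+")))
  if (length(el) != n) stop("parse error: truncated ELEMENTS block", call. = FALSE)
  q <- as.numeric(unlist(strsplit(grabBlock("CHARGES"), "[[:space:]]+")))
  if (length(q) != n || anyNA(q)) stop("parse error: truncated CHARGES block", call. = FALSE)
  popRows <- grabBlock("POPULATIONS", n)
  pop <- t(vapply(strsplit(popRows[seq_len(n)], "[[:space:]]+"),
                  function(t) as.numeric(t[1:3]), numeric(3)))
  if (anyNA(pop)) stop("parse error: malformed POPULATIONS block", call. = FALSE)
  colnames(pop) <- c("s", "p", "d")
  readOverlap <- function(name) {
    m <- matrix(0, n, n)
    body <- grabBlock(name)
    if (length(body)) {
      tr <- t(vapply(strsplit(body, "[[:space:]]+"),
                     function(t) as.numeric(t[1:3]), numeric(3)))
      if (anyNA(tr)) stop("parse error: malformed ", name, " block", call. = FALSE)
      m[cbind(tr[, 1], tr[, 2])] <- tr[, 3]
      m[cbind(tr[, 2], tr[, 1])] <- tr[, 3]
    }
    m
  }
  eps <- list(sigma = readOverlap("OVERLAP_SIGMA"),
              pi = readOverlap("OVERLAP_PI"),
              delta = readOverlap("OVERLAP_DELTA"))
  fun <- function(complex, coords = NULL) {
    if (nAtoms(complex) != n)
      stop("external weight file holds ", n, " atoms; complex has ",
           nAtoms(complex), call. = FALSE)
    pt <- ptableLookup(elementsOf(complex), "external adapter")
    a1 <- cbind(pt$z, pt$group, pt$period, q, pop)
    colnames(a1) <- a1FeatureNames()
    rownames(a1) <- atomIds(complex)
    epsFun <- function(type) eps[[type]]
    list(a1 = a1, omega = buildOmega(q, pop, epsFun))
  }
  new("WeightProvider", name = "external_file", fun = fun)
}
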