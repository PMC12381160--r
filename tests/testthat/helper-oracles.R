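# Independent brute-force oracles. These deliberately re-derive quantities
# from their definitions with naive loops, staying independent of the
# package's computation paths.

oracleA2 <- function(coords, omega, i, centers, cutoff = 8, sigma = 0.0825,
                     include = rep(TRUE, nrow(coords))) {
  v <- numeric(length(centers))
  for (j in seq_len(nrow(coords))) {
    if (j == i || !include[j]) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d > cutoff) next
    v <- v + omega[i, j] * exp(-(d - centers)^2 / (2 * sigma^2)) /
      (sigma * sqrt(2 * pi))
  }
  v
}

oracleA3 <- function(coords, omega, i, centers, angleFn, cutoff = 8,
                     sigma = 0.0825, include = rep(TRUE, nrow(coords))) {
  v <- numeric(length(centers))
  n <- nrow(coords)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == i || k == i || j == k || !include[j] || !include[k]) next
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      dik <- sqrt(sum((coords[i, ] - coords[k, ])^2))
      if (dij > cutoff || dik > cutoff) next
      ct <- sum((coords[j, ] - coords[i, ]) * (coords[k, ] - coords[i, ])) /
        (dij * dik)
      ct <- max(-1, min(1, ct))
      phi <- if (angleFn == "cos") ct else sqrt(1 - ct^2)
      v <- v + omega[i, j] * omega[i, k] * omega[j, k] * phi *
        exp(-(dij - centers)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    }
  }
  v
}

oracleEnrichment <- function(scores, labels, n) {
  ord <- order(-scores)
  topHits <- sum(labels[ord][seq_len(n)])
  topHits / (n * sum(labels) / length(labels))
}

oracleAveragePrecision <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  hits <- 0; total <- 0
  for (r in seq_along(lab)) {
    if (lab[r]) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / sum(lab)
}

rotateCoords <- function(coords, axis = c(1, 2, 3), angle = 0.83,
                         shift = c(0.5, -1.2, 2)) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle); C <- 1 - c0
  Q <- rbind(
    c(c0 + a[1]^2 * C, a[1] * a[2] * C - a[3] * s0, a[1] * a[3] * C + a[2] * s0),
    c(a[2] * a[1] * C + a[3] * s0, c0 + a[2]^2 * C, a[2] * a[3] * C - a[1] * s0),
    c(a[3] * a[1] * C - a[2] * s0, a[3] * a[2] * C + a[1] * s0, c0 + a[3]^2 * C))
  sweep(coords %*% t(Q), 2, shift, "+")
}
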