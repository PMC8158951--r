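# Independent oracles used to cross-check the package's implementations.
# These deliberately use brute force / enumeration, never the code paths
# they verify.

# exhaustive scan over sfSlow: for each candidate fraction, the optimal si0
# is a 1-parameter linear least-squares fit to the mixed attenuation shape
oracleScanTwoComponent <- function(signal, scheme, basis, step = 1e-4) {
  A <- attenuationBasis(scheme, basis)
  sfGrid <- seq(0, 1, by = step)
  G <- A %*% rbind(sfGrid, 1 - sfGrid)          # nMeas x nSf
  si0 <- pmax(0, colSums(G * signal) / colSums(G * G))
  res2 <- colSums((sweep(G, 2, si0, `*`) - signal)^2)
  k <- which.min(res2)
  list(sfSlow = sfGrid[k], si0 = si0[k], rmse = sqrt(res2[k] / nrow(A)))
}

# pairwise-comparison AUC: win = 1, tie = 1/2
bruteAuc <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# exact signed-rank two-sided p by enumeration of all sign assignments
# (assumes no zero differences and no tied |d|)
enumSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  pLe <- mean(Wall <= W)
  pGe <- mean(Wall >= W)
  min(1, 2 * min(pLe, pGe))
}

# exact Mann-Whitney two-sided p by enumeration of all group assignments
# (assumes no ties across the pooled sample)
enumMannWhitneyP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  Wobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  Wall <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  pLe <- mean(Wall <= Wobs)
  pGe <- mean(Wall >= Wobs)
  min(1, 2 * min(pLe, pGe))
}

# bisection on sfSlow over the two-point signal-ratio equation of the
# bi-exponential model
oracleBisectBiExp <- function(s1, s2, b1, b2, adcSlow, adcFast,
                              tol = 1e-12) {
  ratio <- function(sf) {
    g1 <- sf * exp(-b1 * adcSlow * 1e-3) + (1 - sf) * exp(-b1 * adcFast * 1e-3)
    g2 <- sf * exp(-b2 * adcSlow * 1e-3) + (1 - sf) * exp(-b2 * adcFast * 1e-3)
    g2 / g1 - s2 / s1
  }
  stats::uniroot(ratio, c(0, 1), tol = tol)$root
}

# brute-force recount of the exclusion rules on a volume, voxel by voxel
bruteExclusionCount <- function(volume) {
  dat <- volumeData(volume)
  d <- dim(dat)
  m <- measurementTable(volume@scheme)
  bgVals <- c()
  bg <- backgroundMask(volume)
  for (k in seq_len(d[4])) bgVals <- c(bgVals, dat[, , , k][bg])
  floor3 <- 3 * mean(bgVals)
  box <- which(boxMask(volume))
  excluded <- 0L
  for (v in box) {
    ijk <- arrayInd(v, d[1:3])
    s <- dat[ijk[1], ijk[2], ijk[3], ]
    bad <- any(s <= floor3)
    for (te in unique(m$te)) {
      i <- which(m$te == te); i <- i[order(m$b[i])]
      if (any(diff(s[i]) > 0)) bad <- TRUE
    }
    for (b in unique(m$b)) {
      i <- which(m$b == b); i <- i[order(m$te[i])]
      if (any(diff(s[i]) > 0)) bad <- TRUE
    }
    if (bad) excluded <- excluded + 1L
  }
  excluded
}
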