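# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals.

# Brute-force Metropolis replaying the package's documented RNG protocol
# (point index, 3 displacement deviates, acceptance deviate per iteration)
# but recomputing the moved point's assigned energy from scratch each time.
oracleMetropolis <- function(pos, box, cutoff, kSpring, r0, kBT, maxStep,
                             nIter, seed) {
  n <- nrow(pos)
  minImage <- function(d) {
    if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  }
  allDist <- function(p, i, xi) {
    d <- minImage(sweep(p[-i, , drop = FALSE], 2L, xi))
    sqrt(rowSums(d^2))
  }
  nbrs <- lapply(seq_len(n), function(i) {
    d <- allDist(pos, i, pos[i, ])
    (seq_len(n)[-i])[d <= cutoff]
  })
  vharm <- function(r) 0.5 * kSpring * (r - r0)^2
  assigned <- function(p, i) {
    js <- nbrs[[i]]
    d <- minImage(sweep(p[js, , drop = FALSE], 2L, p[i, ]))
    0.5 * sum(vharm(sqrt(rowSums(d^2))))
  }
  set.seed(seed)
  for (it in seq_len(nIter)) {
    i <- min(n, floor(runif(1) * n) + 1L)
    disp <- 2 * maxStep * runif(3) - maxStep
    uAcc <- runif(1)
    pNew <- pos
    pNew[i, ] <- pos[i, ] + disp
    dE <- assigned(pNew, i) - assigned(pos, i)
    if (dE <= 0 || uAcc < exp(-dE / kBT)) {
      if (!is.null(box)) pNew[i, ] <- pNew[i, ] - box * floor(pNew[i, ] / box + 0.5)
      pos <- pNew
    }
  }
  pos
}

# Direct hierarchical amplitude sum: rotations (intrinsic x-y-z Tait-Bryan)
# and translation phases applied leaf by leaf, scalar q at a time.
oracleAssemblySum <- function(leafPositions, placements, qvec) {
  rot <- function(alpha, beta, gamma) {
    a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  total <- 0 + 0i
  for (ri in seq_len(nrow(placements))) {
    A <- rot(placements[ri, 1], placements[ri, 2], placements[ri, 3])
    R <- placements[ri, 4:6]
    qr <- as.numeric(t(A) %*% qvec)     # A^-1 q
    leafAmp <- sum(exp(1i * (leafPositions %*% qr)))
    total <- total + leafAmp * exp(1i * sum(qvec * R))
  }
  total
}

# Closed-form S(q) for a Gaussian-shell pair correlation
# g(r) = 1 + A exp(-(r - r0)^2 / (2 s^2)), valid for r0 >> s (the domain
# extension to the whole real line is then exponentially accurate):
# S(q) = 1 + (4 pi rho A / q) sqrt(2 pi) s exp(-q^2 s^2 / 2)
#            [r0 sin(q r0) + q s^2 cos(q r0)]
oracleGaussianShellS <- function(q, rho, A, r0, s) {
  1 + (4 * pi * rho * A / q) * sqrt(2 * pi) * s * exp(-q^2 * s^2 / 2) *
    (r0 * sin(q * r0) + q * s^2 * cos(q * r0))
}

# Monte Carlo orientation average of the oriented structure factor
# (chunked so large models stay within a small working set).
oracleOrientationAverageS <- function(points, qMag, nDir, seed) {
  set.seed(seed)
  s <- numeric(0)
  left <- nDir
  while (left > 0) {
    m <- min(2000L, left)
    phi <- 2 * pi * runif(m)
    ct <- 2 * runif(m) - 1
    st <- sqrt(1 - ct^2)
    dirs <- cbind(st * cos(phi), st * sin(phi), ct)
    s <- c(s, structureFactorOriented(points, dirs * qMag))
    left <- left - m
  }
  list(mean = mean(s), se = stats::sd(s) / sqrt(nDir))
}

cubicCrystal <- function(reps = 10, a = 3.5)
  buildCrystal(latticeFromConstants(a, a, a, repeats = rep(reps, 3)))
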