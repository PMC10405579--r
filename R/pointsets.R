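#' Lattice specifications
#'
#' A [LatticeSpec-class] is built either directly from three lattice vectors
#' (nm) or from lattice constants a, b, c (nm) and angles alpha, beta, gamma
#' (degrees). The constants are converted to vectors by the standard
#' crystallographic construction: a along x, b in the xy plane at angle
#' gamma from a, and c fixed by alpha, beta and the cell volume.
#'
#' @param a,b,c lattice vectors (length-3 numerics, nm) for
#'   `latticeFromVectors`; lattice constants (nm) for `latticeFromConstants`.
#' @param repeats three positive integers: repetitions along a, b, c.
#' @return A [LatticeSpec-class].
#' @examples
#' latticeFromConstants(3.5, 3.5, 3.5, repeats = c(10, 10, 10))
#' @export
latticeFromVectors <- function(a, b, c, repeats) {
  v <- rbind(as.numeric(a), as.numeric(b), as.numeric(c))
  new("LatticeSpec", vectors = v, repeats = as.integer(repeats))
}

#' @rdname latticeFromVectors
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @export
latticeFromConstants <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                                 repeats = c(1L, 1L, 1L)) {
  if (any(c(a, b, c) <= 0)) stop("lattice constants must be positive", call. = FALSE)
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) stop("angles must lie in (0, 180) degrees", call. = FALSE)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  vol2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol2 <= 0) stop("lattice constants define a degenerate cell", call. = FALSE)
  va <- c(a, 0, 0)
  vb <- c(b * cg, b * sg, 0)
  vc <- c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(vol2) / sg)
  latticeFromVectors(va, vb, vc, repeats)
}

#' Build a crystal docking list from a lattice specification
#'
#' Places one subunit at every integer combination i a + j b + k c
#' (i = 0..n_a - 1, ...), then translates the set so its geometric center
#' (mean position) is at the origin. For orthogonal lattices the periodic
#' box (n_a |a|, n_b |b|, n_c |c|) is attached so that downstream
#' minimum-image computations see the crystal as one period of an infinite
#' lattice; for oblique lattices no box is set.
#'
#' @param spec a [LatticeSpec-class].
#' @return A [PointSet-class] with `prod(repeats)` points.
#' @examples
#' cr <- buildCrystal(latticeFromConstants(3.5, 3.5, 3.5, repeats = c(10, 10, 10)))
#' nPoints(cr)  # 1000
#' @export
buildCrystal <- function(spec) {
  stopifnot(is(spec, "LatticeSpec"))
  v <- spec@vectors
  rep3 <- spec@repeats
  idx <- as.matrix(expand.grid(i = seq_len(rep3[1]) - 1L,
                               j = seq_len(rep3[2]) - 1L,
                               k = seq_len(rep3[3]) - 1L))
  pos <- idx %*% v
  pos <- sweep(pos, 2L, colMeans(pos))
  lens <- sqrt(rowSums(v^2))
  ortho <- all(abs(c(sum(v[1, ] * v[2, ]), sum(v[1, ] * v[3, ]),
                     sum(v[2, ] * v[3, ]))) < 1e-9 * max(lens)^2)
  box <- if (ortho) rep3 * lens else NULL
  pointSet(pos, box = box)
}

#' Add random thermal fluctuations to a point set
#'
#' Uniform mode adds, independently per coordinate, a displacement
#' 2 u v - u with v drawn uniform on [0, 1), so each component lies in
#' [-u, u). Gaussian mode adds a zero-mean normal deviate of standard
#' deviation `sigmaU` per coordinate. The input is unchanged; the result is
#' reproducible under the spec's seed.
#'
#' @param points a [PointSet-class].
#' @param spec a [FluctuationSpec-class].
#' @return A new [PointSet-class] with displaced positions.
#' @examples
#' cr <- buildCrystal(latticeFromConstants(3.5, 3.5, 3.5, repeats = c(3, 3, 3)))
#' th <- thermalize(cr, fluctuationSpec("uniform", u = 0.3, seed = 7))
#' max(abs(positions(th) - positions(cr)))  # < 0.3
#' @export
thermalize <- function(points, spec) {
  stopifnot(is(points, "PointSet"), is(spec, "FluctuationSpec"))
  n <- nPoints(points)
  disp <- withSeed(spec@seed, {
    if (spec@kind == "uniform") {
      v <- matrix(stats::runif(3L * n), n, 3L)
      sweep(2 * v - 1, 2L, spec@u, `*`)
    } else {
      matrix(stats::rnorm(3L * n, sd = spec@sigmaU), n, 3L)
    }
  })
  pointSet(points@positions + disp, orientations = points@orientations,
           box = points@box)
}

# Pair potential V(r) for an MCConfig, vectorized over r.
pairPotential <- function(r, config) {
  if (config@potential == "harmonic") {
    0.5 * config@kSpring * (r - config@r0Spring)^2
  } else {
    sr6 <- (config@sigmaLJ / r)^6
    4 * config@epsilon * (sr6^2 - sr6)
  }
}

# Static nearest-neighbor list from the initial configuration.
neighborList <- function(pos, cutoff, box = NULL) {
  n <- nrow(pos)
  nn <- vector("list", n)
  for (i in seq_len(n)) {
    d <- distancesFrom(pos, i, box)
    others <- seq_len(n)[-i]
    nn[[i]] <- others[d <= cutoff]
    if (length(nn[[i]]) == 0L)
      stop(sprintf("point %d has no neighbors within the cutoff %.4g nm", i, cutoff),
           call. = FALSE)
  }
  nn
}

# Minimum-image displacement of points `js` relative to point coordinates `xi`.
neighborDistances <- function(pos, js, xi, box) {
  d <- sweep(pos[js, , drop = FALSE], 2L, xi)
  if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d^2))
}

#' Total assigned potential energy of a point set
#'
#' Sums the pair potential over the static nearest-neighbor list with the
#' interaction-sharing convention of [mcSimulate()] (each pair counted with
#' weight 1/2 per member, i.e. once in total).
#'
#' @param points a [PointSet-class].
#' @param config an [MCConfig-class] (supplies potential and cutoff).
#' @param neighbors optional precomputed neighbor list (positions indices).
#' @return total energy (same units as the potential).
#' @export
potentialEnergy <- function(points, config, neighbors = NULL) {
  pos <- points@positions
  if (is.null(neighbors)) neighbors <- neighborList(pos, config@neighborCutoff, points@box)
  e <- 0
  for (i in seq_along(neighbors)) {
    d <- neighborDistances(pos, neighbors[[i]], pos[i, ], points@box)
    e <- e + 0.5 * sum(pairPotential(d, config))
  }
  e
}

#' Metropolis Monte Carlo thermalization of a point set
#'
#' Runs Metropolis iterations against a harmonic or Lennard-Jones pair
#' potential acting between static nearest neighbors (selected once from the
#' initial configuration by `neighborCutoff`). Each iteration picks a random
#' point, proposes a displacement with components uniform in
#' [-maxStep, maxStep), computes the energy cost Delta E as half the summed
#' pair-energy change over the point's neighbors (each interaction is shared
#' between the interacting pair), and accepts with probability
#' min(1, exp(-Delta E / kBT)). Minimum-image distances and coordinate
#' wrapping apply when the point set carries a periodic box. Reproducible
#' under the config seed; `maxIterations = 0` returns the input unchanged.
#'
#' RNG protocol per iteration (all from one seeded stream): point index via
#' one uniform deviate, three uniform deviates for the displacement, one
#' uniform deviate for the acceptance test (always drawn).
#'
#' @param points a [PointSet-class] with at least 2 points.
#' @param config an [MCConfig-class].
#' @return the final [PointSet-class].
#' @export
mcSimulate <- function(points, config) {
  stopifnot(is(points, "PointSet"), is(config, "MCConfig"))
  n <- nPoints(points)
  if (n < 2L) stop("mcSimulate needs at least 2 points", call. = FALSE)
  pos <- points@positions
  box <- points@box
  nn <- neighborList(pos, config@neighborCutoff, box)
  kBT <- config@kBT
  step <- config@maxStep
  pos <- withSeed(config@seed, {
    for (it in seq_len(config@maxIterations)) {
      i <- min(n, floor(stats::runif(1) * n) + 1L)
      disp <- 2 * step * stats::runif(3L) - step
      uAcc <- stats::runif(1)
      js <- nn[[i]]
      dOld <- neighborDistances(pos, js, pos[i, ], box)
      xNew <- pos[i, ] + disp
      dNew <- neighborDistances(pos, js, xNew, box)
      dE <- 0.5 * (sum(pairPotential(dNew, config)) - sum(pairPotential(dOld, config)))
      if (dE <= 0 || uAcc < exp(-dE / kBT)) {
        if (!is.null(box)) xNew <- xNew - box * floor(xNew / box + 0.5)
        pos[i, ] <- xNew
      }
    }
    pos
  })
  pointSet(pos, orientations = points@orientations, box = box)
}
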