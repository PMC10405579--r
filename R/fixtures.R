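#' Programmatic test structures
#'
#' Deterministic generators for the point models used throughout the
#' examples and tests; every model is built in code, no external data.
#'
#' * `cubic_crystal`: simple cubic lattice, edge `a` (nm), `repeats` per
#'   axis (periodic box attached).
#' * `triclinic_crystal`: general lattice from constants
#'   `a, b, c, alpha, beta, gamma` and `repeats`.
#' * `graphene_sheet`: honeycomb net in the xz plane with lattice constant
#'   `a` (default 0.246 nm) and the two-atom basis; `nCells` unit cells per
#'   in-plane direction, a single repetition along y (the beam direction).
#' * `point_helix`: `n` points on a helix along z with given `radius`,
#'   `rise` and `twist` per residue; `nStrands = 2` adds a second strand
#'   offset by 180 degrees.
#' * `ideal_gas`: `n` uniform random points in a periodic cubic box of edge
#'   `boxEdge` (seeded).
#'
#' @param kind fixture kind (see above).
#' @param a lattice constant (nm).
#' @param b,c,alpha,beta,gamma triclinic constants (nm, degrees).
#' @param repeats repeats per axis (scalar recycled to 3).
#' @param nCells graphene unit cells per in-plane direction.
#' @param radius,rise,twist helix radius (nm), rise per residue (nm), twist
#'   per residue (degrees).
#' @param n number of points (helix residues per strand / gas particles).
#' @param nStrands 1 or 2 helix strands.
#' @param boxEdge ideal-gas box edge (nm).
#' @param seed RNG seed for the stochastic kinds.
#' @return a [PointSet-class].
#' @examples
#' nPoints(makeFixture("graphene_sheet", nCells = 25))  # 2 * 25 * 25
#' @export
makeFixture <- function(kind = c("cubic_crystal", "triclinic_crystal",
                                 "graphene_sheet", "point_helix", "ideal_gas"),
                        a = 3.5, b = a, c = a, alpha = 90, beta = 90,
                        gamma = 90, repeats = 10L, nCells = 25L,
                        radius = 1, rise = 0.34, twist = 36, n = 10L,
                        nStrands = 1L, boxEdge = 50, seed = 1L) {
  kind <- match.arg(kind)
  if (length(repeats) == 1L) repeats <- rep(repeats, 3L)
  switch(kind,
    cubic_crystal = buildCrystal(latticeFromConstants(a, a, a, repeats = repeats)),
    triclinic_crystal = buildCrystal(latticeFromConstants(a, b, c, alpha, beta,
                                                          gamma, repeats = repeats)),
    graphene_sheet = {
      nCells <- as.integer(nCells)
      if (nCells < 1L) stop("nCells must be >= 1", call. = FALSE)
      if (missing(a)) a <- 0.246        # graphene lattice constant (nm)
      # honeycomb in the xz plane: primitive vectors at 60 degrees, basis
      # atom at (a1 + a3) / 3 (nearest-neighbor distance a / sqrt(3))
      a1 <- c(a, 0, 0)
      a3 <- c(a / 2, 0, a * sqrt(3) / 2)
      idx <- as.matrix(expand.grid(i = seq_len(nCells) - 1L,
                                   k = seq_len(nCells) - 1L))
      cells <- idx %*% rbind(a1, a3)
      basis <- rbind(c(0, 0, 0), (a1 + a3) / 3)
      pos <- rbind(cells, sweep(cells, 2L, basis[2, ], `+`))
      pos <- sweep(pos, 2L, colMeans(pos))
      pointSet(pos)
    },
    point_helix = {
      n <- as.integer(n)
      if (!nStrands %in% c(1L, 2L)) stop("nStrands must be 1 or 2", call. = FALSE)
      k <- seq_len(n) - 1L
      ang <- k * twist * pi / 180
      one <- function(offset) cbind(radius * cos(ang + offset),
                                    radius * sin(ang + offset), k * rise)
      pos <- one(0)
      if (nStrands == 2L) pos <- rbind(pos, one(pi))
      pos <- sweep(pos, 2L, colMeans(pos))
      pointSet(pos)
    },
    ideal_gas = {
      n <- as.integer(n)
      pos <- withSeed(seed, matrix(stats::runif(3L * n, 0, boxEdge), n, 3L))
      pointSet(pos, box = rep(boxEdge, 3L))
    })
}
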