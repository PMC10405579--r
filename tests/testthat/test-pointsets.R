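test_that("buildCrystal places, counts and centers lattice points", {
  cr <- buildCrystal(latticeFromConstants(3.5, 3.5, 3.5, repeats = c(10, 10, 10)))
  expect_equal(nPoints(cr), 1000L)
  expect_equal(colMeans(positions(cr)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(boxEdges(cr), c(35, 35, 35))
  # nearest-neighbor distance is the lattice parameter
  d <- dist(positions(cr))
  expect_equal(min(d), 3.5, tolerance = 1e-12)

  # single repeat: one point at the origin regardless of the cell
  one <- buildCrystal(latticeFromConstants(2, 3, 4, 80, 95, 100, repeats = c(1, 1, 1)))
  expect_equal(positions(one), matrix(0, 1, 3))
})

test_that("lattice constants and explicit vectors build identical crystals", {
  a <- buildCrystal(latticeFromConstants(3, 4, 5, 90, 90, 90, repeats = c(2, 2, 2)))
  b <- buildCrystal(latticeFromVectors(c(3, 0, 0), c(0, 4, 0), c(0, 0, 5),
                                       repeats = c(2, 2, 2)))
  sortRows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(sortRows(positions(a)), sortRows(positions(b)), tolerance = 1e-12)
})

test_that("degenerate lattices and invalid parameters are rejected", {
  expect_error(latticeFromConstants(-1, 1, 1, repeats = c(1, 1, 1)), "positive")
  expect_error(latticeFromConstants(1, 1, 1, alpha = 0, repeats = c(1, 1, 1)), "angles")
  expect_error(latticeFromVectors(c(1, 0, 0), c(2, 0, 0), c(0, 0, 1),
                                  repeats = c(1, 1, 1)), "degenerate|coplanar")
  expect_error(latticeFromVectors(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                  repeats = c(0, 1, 1)))
})

test_that("pairwise-distance multiset is invariant under the centering shift", {
  spec <- latticeFromConstants(2, 3, 4, repeats = c(3, 2, 2))
  cr <- buildCrystal(spec)
  shifted <- pointSet(sweep(positions(cr), 2L, c(5, -2, 1), `+`))
  expect_equal(sort(as.numeric(dist(positions(cr)))),
               sort(as.numeric(dist(positions(shifted)))), tolerance = 1e-10)
})

test_that("thermalize respects the fluctuation law and is reproducible", {
  cr <- cubicCrystal(10)
  # zero fluctuation is the identity
  expect_equal(positions(thermalize(cr, fluctuationSpec("uniform", u = 0))),
               positions(cr))
  expect_equal(positions(thermalize(cr, fluctuationSpec("gaussian", sigmaU = 0))),
               positions(cr))
  # uniform displacements live in [-u, u) componentwise
  sp <- fluctuationSpec("uniform", u = 0.3, seed = 11)
  th <- thermalize(cr, sp)
  disp <- positions(th) - positions(cr)
  expect_true(all(disp >= -0.3 & disp < 0.3))
  expect_gt(max(abs(disp)), 0.25)   # fluctuations actually fill the domain
  # bit-reproducible under a fixed seed; input untouched
  expect_identical(positions(thermalize(cr, sp)), positions(th))
  expect_equal(boxEdges(th), boxEdges(cr))
})

test_that("gaussian thermalization matches its nominal width at large n", {
  many <- pointSet(matrix(0, 1e5, 3))
  th <- thermalize(many, fluctuationSpec("gaussian", sigmaU = 0.3, seed = 5))
  expect_equal(sd(as.numeric(positions(th))), 0.3, tolerance = 0.02)
})

test_that("Metropolis at vanishing kBT never raises the energy", {
  cr <- cubicCrystal(4)
  start <- thermalize(cr, fluctuationSpec("uniform", u = 0.2, seed = 3))
  cfg <- mcConfig("harmonic", kSpring = 1, r0Spring = 3.5, kBT = 1e-12,
                  maxIterations = 2000L, maxStep = 0.1, neighborCutoff = 3.6,
                  seed = 21)
  out <- mcSimulate(start, cfg)
  expect_lte(potentialEnergy(out, cfg), potentialEnergy(start, cfg))
})

test_that("mcSimulate with zero iterations is the identity", {
  cr <- cubicCrystal(3)
  cfg <- mcConfig("harmonic", kSpring = 1, r0Spring = 3.5, kBT = 1,
                  maxIterations = 0L, maxStep = 0.1, neighborCutoff = 3.6, seed = 1)
  expect_identical(positions(mcSimulate(cr, cfg)), positions(cr))
})

test_that("mcSimulate matches an independent brute-force Metropolis oracle", {
  cr <- cubicCrystal(5)
  cfg <- mcConfig("harmonic", kSpring = 2, r0Spring = 3.5, kBT = 0.05,
                  maxIterations = 5000L, maxStep = 0.15, neighborCutoff = 3.6,
                  seed = 42)
  got <- mcSimulate(cr, cfg)
  want <- oracleMetropolis(positions(cr), boxEdges(cr), 3.6, 2, 3.5, 0.05,
                           0.15, 5000L, 42)
  expect_equal(positions(got), want, tolerance = 1e-12)
  # the run actually moved points
  expect_gt(mean(abs(positions(got) - positions(cr))), 0)
})

test_that("mcSimulate accepts nearly everything at very high temperature", {
  cr <- cubicCrystal(3)
  cfg <- mcConfig("harmonic", kSpring = 1, r0Spring = 3.5, kBT = 1e9,
                  maxIterations = 500L, maxStep = 0.05, neighborCutoff = 3.6,
                  seed = 9)
  out <- mcSimulate(cr, cfg)
  # with acceptance ratio -> 1, essentially every point has moved
  moved <- rowSums(abs(positions(out) - positions(cr))) > 0
  expect_gt(mean(moved), 0.95)
})

test_that("mcSimulate validates isolated points and Lennard-Jones runs", {
  p <- pointSet(rbind(c(0, 0, 0), c(10, 0, 0)))
  cfg <- mcConfig("harmonic", neighborCutoff = 1, seed = 1)
  expect_error(mcSimulate(p, cfg), "point 1")
  lj <- mcConfig("lennard_jones", epsilon = 1, sigmaLJ = 3.1, kBT = 0.1,
                 maxIterations = 200L, maxStep = 0.05, neighborCutoff = 3.6, seed = 2)
  out <- mcSimulate(cubicCrystal(3), lj)
  expect_true(all(is.finite(positions(out))))
})
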