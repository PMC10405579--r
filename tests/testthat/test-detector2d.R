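test_that("single-orientation images of isotropic sources are radially symmetric", {
  gr <- fillGrid(sphereModel(1.2), qMax = 6, nShells = 12)
  img <- singleOrientationPattern(gr, nPoints = 32, qLimit = 4)
  v <- imageValues(img)
  expect_true(all(v >= 0))
  ax <- imageAxes(img)
  # intensity depends on pixel radius only
  rad <- sqrt(outer(ax$qZ^2, ax$qPerp^2, `+`))
  ord <- order(as.numeric(rad))
  expect_lt(max(abs(diff(as.numeric(v)[ord])[diff(sort(as.numeric(rad))) < 1e-9])),
            1e-9)
  # quadrant mirror symmetry for the isotropic image
  expect_equal(v, v[rev(seq_len(nrow(v))), ], tolerance = 1e-12)
  expect_equal(v, v[, rev(seq_len(ncol(v)))], tolerance = 1e-12)
})

test_that("out-of-range pixels are masked and zero, and odd sizes rejected", {
  gr <- fillGrid(sphereModel(1.2), qMax = 3, nShells = 6)
  img <- singleOrientationPattern(gr, nPoints = 16, qLimit = 3)
  m <- imageMask(img)
  expect_true(any(m))                       # detector corners exceed q_max
  expect_true(all(imageValues(img)[m] == 0))
  expect_error(singleOrientationPattern(gr, 15, 2), "even")
  expect_error(fiberPattern(gr, 15, 2), "even")
})

test_that("phi' and phi' + 180 give q_perp-mirrored images", {
  helix <- makeFixture("point_helix", radius = 0.8, rise = 0.4, twist = 40,
                       n = 12)
  gr <- fillGrid(helix, qMax = 8, nShells = 16, scatteringLength = 1)
  a <- imageValues(singleOrientationPattern(gr, 24, 5, phiPrime = 30))
  b <- imageValues(singleOrientationPattern(gr, 24, 5, phiPrime = 210))
  expect_equal(a, b[, rev(seq_len(ncol(b)))], tolerance = 1e-9)
})

test_that("fiber pattern of an azimuthally symmetric source matches the slice", {
  gr <- fillGrid(sphereModel(1.5), qMax = 6, nShells = 12)
  single <- singleOrientationPattern(gr, 20, 4)
  fib <- fiberPattern(gr, 20, 4, relTol = 1e-3, maxSamples = 256, seed = 2)
  expect_equal(imageValues(fib), imageValues(single), tolerance = 1e-6)
  expect_true(fib@metadata$converged)
})

test_that("stacked point helices give a mirror-symmetric layer-line pattern", {
  helix <- makeFixture("point_helix", radius = 1, rise = 0.34, twist = 36, n = 10)
  stack <- assemblyNode(list(helix),
                        list(rbind(c(0, 0, 0, 0, 0, -3.5), c(0, 0, 0, 0, 0, 0),
                                   c(0, 0, 0, 0, 0, 3.5))))
  img <- suppressWarnings(   # tight budget: convergence flag expected
    fiberPattern(stack, nPoints = 32, qLimit = 10, relTol = 5e-3,
                 maxSamples = 4096, seed = 11, scatteringLength = 1))
  v <- imageValues(img)
  expect_true(all(v >= 0))
  # full-domain azimuthal average: mirror symmetry in q_perp and q_z
  relErr <- function(x, y) max(abs(x - y)) / max(x)
  expect_lt(relErr(v, v[, rev(seq_len(ncol(v)))]), 0.05)
  expect_lt(relErr(v, v[rev(seq_len(nrow(v))), ]), 0.05)
  # 'X' shape: on the first helical layer line the maximum sits off-meridian
  ax <- imageAxes(img)
  pitch <- 0.34 * 10                       # one full turn per 10 residues
  row <- which.min(abs(ax$qZ - 2 * pi / pitch))
  offAxis <- abs(ax$qPerp[which.max(v[row, ])])
  expect_gt(offAxis, 1)
  # while the equator peaks on the meridian side (small |q_perp|)
  eq <- which.min(abs(ax$qZ))
  expect_lt(abs(ax$qPerp[which.max(v[eq, ])]), offAxis)
})

test_that("restricting the azimuth domain recovers the single orientation", {
  helix <- makeFixture("point_helix", radius = 0.8, rise = 0.4, twist = 40, n = 8)
  gr <- fillGrid(helix, qMax = 6, nShells = 12, scatteringLength = 1)
  single <- singleOrientationPattern(gr, 16, 4, phiPrime = 25)
  narrow <- fiberPattern(gr, 16, 4, phiDomain = c(25 - 0.01, 25 + 0.01),
                         relTol = 1e-3, maxSamples = 512, seed = 6)
  expect_equal(imageValues(narrow), imageValues(single), tolerance = 1e-3)
})

test_that("fiber averaging commutes with intensity scaling of the source", {
  helix <- makeFixture("point_helix", radius = 1, rise = 0.34, twist = 36, n = 8)
  a <- suppressWarnings(fiberPattern(helix, 16, 5, relTol = 5e-3,
                                     maxSamples = 512, seed = 9,
                                     scatteringLength = 1))
  b <- suppressWarnings(fiberPattern(helix, 16, 5, relTol = 5e-3,
                                     maxSamples = 512, seed = 9,
                                     scatteringLength = 3))
  expect_equal(imageValues(b), 9 * imageValues(a), tolerance = 1e-9)
})
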