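test_that("grid filling: isotropy, constancy and node counts", {
  gp <- fillGrid(pointScatterer(2.5), qMax = 4, nShells = 4)
  expect_true(all(gp@values == 2.5 + 0i))
  gs <- fillGrid(sphereModel(1.5), qMax = 4, nShells = 5)
  # all angular samples on a shell are equal for an isotropic source
  for (i in 0:5) {
    off <- gs@rowOffset[[i + 1]]
    nph <- gs@rowNphi[[i + 1]]
    vals <- gs@values[seq(off[1], off[length(off)] + nph[length(nph)] - 1L)]
    expect_lt(diff(range(Re(vals))), 1e-12)
  }
})

test_that("graphene-sheet grid nodes equal the direct hierarchical sum", {
  sheet <- makeFixture("graphene_sheet", nCells = 25)
  expect_equal(nPoints(sheet), 1250L)
  expect_true(all(positions(sheet)[, 2] == 0))
  gr <- fillGrid(sheet, qMax = 3, nShells = 6, scatteringLength = 1)
  # compare a scattering of nodes against an independent direct sum
  lay <- oriscat:::gridLayout(3, 6L)
  coords <- oriscat:::gridNodeCoords(lay)
  qvecs <- oriscat:::polarToCartesian(coords)
  set.seed(4)
  pick <- sample(nrow(qvecs), 40)
  placements <- matrix(0, 1, 6)
  for (k in pick) {
    want <- oracleAssemblySum(positions(sheet), placements, qvecs[k, ])
    expect_equal(gr@values[k], want, tolerance = 1e-9)
  }
})

test_that("assembly amplitudes: translation phase and two-point closed form", {
  b <- 1.3
  # a translated subunit keeps |F|: pure phase factor
  sph <- sphereModel(1.5)
  asm <- assemblyNode(list(sph), list(matrix(c(0, 0, 0, 2, -1, 3), 1)))
  qv <- rbind(c(0.3, 0.4, 0.5), c(1, 0, 2), c(0, 3, 0))
  expect_equal(Mod(amplitudeAt(asm, qv)), Mod(amplitudeAt(sph, qv)),
               tolerance = 1e-12)
  # two identical point scatterers at +/- d/2 on z: F = 2 b cos(q_z d / 2)
  d <- 2.4
  two <- assemblyNode(list(pointScatterer(b)),
                      list(rbind(c(0, 0, 0, 0, 0, d / 2), c(0, 0, 0, 0, 0, -d / 2))))
  qz <- seq(0, 5, 0.25)
  expect_equal(Re(amplitudeAt(two, cbind(0, 0, qz))), 2 * b * cos(qz * d / 2),
               tolerance = 1e-12)
  expect_equal(max(abs(Im(amplitudeAt(two, cbind(0, 0, qz))))), 0, tolerance = 1e-12)
})

test_that("Tait-Bryan rotations act intrinsically in x-y-z order", {
  # rotating a z-axis cylinder by beta = 90 about y puts its axis along x:
  # the amplitude at q along z must equal the unrotated amplitude at q along x
  cyl <- cylinderModel(0.17, 3.2)
  rot <- assemblyNode(list(cyl), list(matrix(c(0, 90, 0, 0, 0, 0), 1)))
  q <- seq(0.5, 4, 0.5)
  expect_equal(Re(amplitudeAt(rot, cbind(0, 0, q))),
               Re(amplitudeAt(cyl, cbind(q, 0, 0))), tolerance = 1e-9)
  # gamma (about z) leaves a z-axis cylinder invariant
  rotz <- assemblyNode(list(cyl), list(matrix(c(0, 0, 35, 0, 0, 0), 1)))
  qv <- rbind(c(1, 0.5, 2), c(0.2, 1, 0.1))
  expect_equal(amplitudeAt(rotz, qv), amplitudeAt(cyl, qv), tolerance = 1e-9)
})

test_that("grid algebra is node-wise, commutative and linear", {
  a <- fillGrid(sphereModel(1.0), qMax = 3, nShells = 4)
  b <- fillGrid(pointScatterer(1), qMax = 3, nShells = 4)
  expect_equal(multiplyGrids(a, b)@values, a@values)        # b is identically 1
  expect_equal(multiplyGrids(a, a)@values, a@values^2)
  expect_equal(sumGrids(a, b)@values, sumGrids(b, a)@values)
  zero <- fillGrid(pointScatterer(0), qMax = 3, nShells = 4)
  expect_equal(sumGrids(a, zero)@values, a@values)
  # union of sub-assemblies = sum of their grids, node-exact
  p1 <- assemblyNode(list(pointScatterer(1)), list(matrix(c(0, 0, 0, 0, 0, 1), 1)))
  p2 <- assemblyNode(list(pointScatterer(1)), list(matrix(c(0, 0, 0, 0, 0, -1), 1)))
  both <- assemblyNode(list(pointScatterer(1)),
                       list(rbind(c(0, 0, 0, 0, 0, 1), c(0, 0, 0, 0, 0, -1))))
  expect_equal(sumGrids(fillGrid(p1, 3, 4), fillGrid(p2, 3, 4))@values,
               fillGrid(both, 3, 4)@values, tolerance = 1e-12)
  expect_error(multiplyGrids(a, fillGrid(sphereModel(1), 3, 5)), "layouts")
})

test_that("interpolation is exact at nodes and isotropic for isotropic grids", {
  sph <- sphereModel(1.2)
  gr <- fillGrid(sph, qMax = 5, nShells = 8)
  lay <- oriscat:::gridLayout(5, 8L)
  qvecs <- oriscat:::polarToCartesian(oriscat:::gridNodeCoords(lay))
  set.seed(2)
  pick <- sample(nrow(qvecs), 60)
  expect_equal(interpolateAmplitude(gr, qvecs[pick, ]), gr@values[pick],
               tolerance = 1e-12)
  # direction independence for an isotropic source
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1) / sqrt(3), c(-0.6, 0.8, 0))
  v <- interpolateAmplitude(gr, dirs * 2.3)
  expect_lt(diff(range(Re(v))), 1e-10)
  expect_error(interpolateAmplitude(gr, c(6, 0, 0)), "q_max")
})

test_that("interpolation error falls at least fourfold per shell doubling", {
  gauss <- function(qv) exp(-rowSums(qv^2) / 2)   # smooth isotropic amplitude
  evalErr <- function(nShells) {
    lay <- oriscat:::gridLayout(4, as.integer(nShells))
    qvecs <- oriscat:::polarToCartesian(oriscat:::gridNodeCoords(lay))
    gr <- new("ReciprocalGrid", qMax = 4, nShells = as.integer(nShells),
              shellQ = lay$shellQ, shellTheta = lay$shellTheta,
              rowNphi = lay$rowNphi, rowOffset = lay$rowOffset,
              values = complex(real = gauss(qvecs)))
    set.seed(10)
    qs <- runif(400, 0.8, 3.2)      # interior radii: cubic radial stencil
    dirs <- matrix(rnorm(1200), 400, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    test <- dirs * qs
    max(abs(Re(interpolateAmplitude(gr, test)) - gauss(test)))
  }
  e1 <- evalErr(10); e2 <- evalErr(20)
  expect_gte(e1 / e2, 4)
})

test_that("orientation averaging: isotropic, two-point and crystal oracles", {
  qg <- seq(0.2, 3, 0.2)
  # isotropic source: equals |F(q)|^2 and converges immediately
  sph <- sphereModel(1.5)
  iso <- orientationAverage(sph, qg, seed = 3)
  expect_true(curveMetadata(iso)$converged)
  expect_equal(intensities(iso), Re(amplitudeAt(sph, cbind(qg, 0, 0)))^2,
               tolerance = 1e-9)
  # two-point assembly: I(q) = 2 b^2 (1 + sinc(q d))
  d <- 2.0; b <- 1.0
  two <- assemblyNode(list(pointScatterer(b)),
                      list(rbind(c(0, 0, 0, 0, 0, d / 2), c(0, 0, 0, 0, 0, -d / 2))))
  got <- suppressWarnings(   # tight budget: convergence flag expected
    orientationAverage(two, qg, relTol = 1e-4, maxSamples = 2^15, seed = 5))
  want <- 2 * b^2 * (1 + sin(qg * d) / (qg * d))
  expect_equal(intensities(got), want, tolerance = 0.02)
})

test_that("global rigid motion leaves the orientation average unchanged", {
  pts <- pointSet(matrix(runif(24, -2, 2), 8, 3))
  qg <- c(0.5, 1.5, 2.5)
  base <- suppressWarnings(
    orientationAverage(pts, qg, relTol = 1e-4, maxSamples = 2^14, seed = 7))
  moved <- assemblyNode(list(pts), list(matrix(c(20, 40, 60, 5, -3, 2), 1)))
  same <- suppressWarnings(
    orientationAverage(moved, qg, relTol = 1e-4, maxSamples = 2^14, seed = 7))
  expect_equal(intensities(same), intensities(base), tolerance = 0.03)
})

test_that("grid persistence round-trips exactly", {
  gr <- fillGrid(cylinderModel(0.3, 2.5), qMax = 4, nShells = 5)
  path <- tempfile(fileext = ".grid")
  writeGrid(gr, path)
  back <- readGrid(path)
  expect_identical(back@values, gr@values)
  expect_equal(back@qMax, gr@qMax)
  expect_equal(back@nShells, gr@nShells)
})
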