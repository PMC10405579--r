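test_that("oriented structure factor reproduces closed-form interference", {
  # single point anywhere: S = 1
  expect_equal(structureFactorOriented(pointSet(c(2, -1, 3)),
                                       rbind(c(1, 2, 3), c(0, 0, 0))), c(1, 1))
  # q = 0: all phases unity, S = N
  p8 <- pointSet(matrix(rnorm(24), 8, 3))
  expect_equal(structureFactorOriented(p8, c(0, 0, 0)), 8)
  # two points d apart along z at q_z = pi / d: destructive interference
  d <- 1.7
  p2 <- pointSet(rbind(c(0, 0, 0), c(0, 0, d)))
  expect_equal(structureFactorOriented(p2, c(0, 0, pi / d)), 0, tolerance = 1e-12)
  expect_equal(structureFactorOriented(p2, c(0, 0, 2 * pi / d)), 2, tolerance = 1e-12)
})

test_that("Debye sum: limits, positivity and rigid-motion invariance", {
  qg <- seq(0, 6, 0.1)
  expect_equal(sValues(sqFromModel(pointSet(c(1, 2, 3)), qg)), rep(1, length(qg)))
  p <- pointSet(matrix(runif(30, -2, 2), 10, 3))
  sq <- sqFromModel(p, qg)
  expect_equal(sValues(sq)[1], 10)
  expect_true(all(sValues(sq) >= 0))
  # rigid rotation + translation leave S(q) unchanged
  A <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  moved <- pointSet(sweep(positions(p) %*% A, 2L, c(4, -1, 2), `+`))
  expect_equal(sValues(sqFromModel(moved, qg)), sValues(sq), tolerance = 1e-9)
})

test_that("Debye sum equals the orientation average of the oriented S", {
  qg <- 1.0
  for (model in list(pointSet(rbind(c(0, 0, -2), c(0, 0, 0), c(0, 0, 2))),
                     pointSet(matrix(runif(24, -3, 3), 8, 3)))) {
    iso <- sValues(sqFromModel(model, qg))
    mc <- oracleOrientationAverageS(model, qg, nDir = 1e5, seed = 13)
    expect_lt(abs(iso - mc$mean), 3 * mc$se)
  }
})

test_that("histogrammed and exact Debye sums agree", {
  p <- pointSet(matrix(runif(90, -5, 5), 30, 3))
  qg <- seq(0.2, 8, 0.2)
  d <- as.numeric(dist(positions(p)))
  exact <- sValues(sqFromModel(p, qg))
  hist1 <- oriscat:::debyeFromDistances(d, 30L, qg, histogram = TRUE)
  expect_equal(hist1, exact, tolerance = 1e-4)
})

test_that("thermal averaging needs a fluctuation spec and damps oscillations", {
  cr <- cubicCrystal(4)
  qg <- seq(0.2, 4, 0.05)
  expect_error(sqFromModel(cr, qg, nThermal = 5), "FluctuationSpec")
  rigid <- sValues(sqFromModel(cr, qg))
  warm <- sValues(sqFromModel(cr, qg, nThermal = 8,
                              fluct = fluctuationSpec("gaussian", sigmaU = 0.25,
                                                      seed = 31)))
  # thermal disorder reduces the Bragg peak amplitude
  expect_lt(max(warm), max(rigid))
  # and the averaging is reproducible
  warm2 <- sValues(sqFromModel(cr, qg, nThermal = 8,
                               fluct = fluctuationSpec("gaussian", sigmaU = 0.25,
                                                       seed = 31)))
  expect_identical(warm, warm2)
})

test_that("intensity inversion recovers S for ideal and decorated systems", {
  qg <- seq(0.1, 4, 0.05)
  ff <- solutionFormFactor(sphereModel(1.5), qg)
  # I = N |f|^2 exactly -> S = 1 everywhere
  ideal <- scatteringCurve(qg, 12 * intensities(ff))
  expect_equal(sValues(sqFromIntensity(ideal, ff, 12L)), rep(1, length(qg)))
  # grid mismatch and non-positive form factors are rejected
  expect_error(sqFromIntensity(scatteringCurve(qg + 0.01, intensities(ff)), ff, 2L),
               "share one q grid")
  badFF <- scatteringCurve(qg, c(0, intensities(ff)[-1]))
  expect_error(sqFromIntensity(ideal, badFF, 12L), "0.1")
})

test_that("transforming a flat g(r) gives S identical to 1", {
  flat <- rdfCurve(seq(0.025, 20, 0.05), rep(1, 400), rhoB = 0.05)
  s <- sqFromGr(flat, seq(0, 5, 0.1), method = "simpson")
  expect_equal(sValues(s), rep(1, 51), tolerance = 1e-12)
  sd <- sqFromGr(flat, method = "dst")
  expect_equal(sValues(sd), rep(1, length(sValues(sd))), tolerance = 1e-12)
})

test_that("Gaussian-shell g(r) transforms to its closed-form S(q)", {
  rho <- 0.02; A <- 2; r0 <- 4; s <- 0.3
  rg <- seq(0.005, 16, 0.01)
  g <- 1 + A * exp(-(rg - r0)^2 / (2 * s^2))
  rdf <- rdfCurve(rg, g, rhoB = rho)
  qg <- seq(0.2, 6, 0.2)
  got <- sValues(sqFromGr(rdf, qg, method = "simpson"))
  want <- oracleGaussianShellS(qg, rho, A, r0, s)
  expect_equal(got, want, tolerance = 1e-4)
  # the q = 0 analytic limit agrees with the shell's excess volume integral
  s0 <- sValues(sqFromGr(rdf, 0, method = "simpson"))
  want0 <- 1 + 4 * pi * rho * A * sqrt(2 * pi) * s * (r0^2 + s^2)
  expect_equal(s0, want0, tolerance = 1e-4)
})

test_that("simpson and dst transforms agree on smooth inputs", {
  rho <- 0.02
  rg <- seq(0.005, 16, 0.01)
  g <- 1 + 2 * exp(-(rg - 4)^2 / 0.18)
  rdf <- rdfCurve(rg, g, rhoB = rho)
  qNat <- qValues(sqFromGr(rdf, method = "dst"))
  keep <- qNat > 0.3 & qNat < 6
  sSimp <- sValues(sqFromGr(rdf, qNat[keep], method = "simpson"))
  sDst <- sValues(sqFromGr(rdf, method = "dst"))[keep]
  expect_lt(max(abs(sSimp - sDst)) / max(abs(sSimp)), 0.01)
})
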