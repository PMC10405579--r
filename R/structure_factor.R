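#' Oriented structure factor of a point model
#'
#' For each reciprocal-space vector, returns
#' S(q) = (1/N) |sum_i exp(i q . r_i)|^2 — the single-orientation
#' interference function of the subunit arrangement (no form-factor
#' weighting).
#'
#' @param points a [PointSet-class].
#' @param qvecs a length-3 vector or n x 3 matrix of q vectors (nm^-1).
#' @return numeric vector of S values, one per q vector.
#' @examples
#' p <- pointSet(rbind(c(0, 0, 0), c(0, 0, 2)))
#' structureFactorOriented(p, c(0, 0, pi / 2))  # destructive interference: 0
#' @export
structureFactorOriented <- function(points, qvecs) {
  stopifnot(is(points, "PointSet"))
  qvecs <- asQMatrix(qvecs)
  amp <- amplitudeAt(points, qvecs, scatteringLength = 1)
  Mod(amp)^2 / nPoints(points)
}

# Debye sum over a pair-distance vector: S(q) = 1 + (2/N) sum_pairs sinc(q d).
# Above `histThreshold` points the distances are histogrammed on bins of
# width `binWidth` (induced relative error < 1e-4 for the q ranges used).
debyeFromDistances <- function(d, n, qGrid, histogram = FALSE,
                               binWidth = 1e-3) {
  if (histogram) {
    k <- floor(d / binWidth) + 1L
    counts <- tabulate(k)
    nz <- which(counts > 0L)
    d <- (nz - 0.5) * binWidth
    w <- counts[nz]
  } else {
    # exact sum; merge degenerate distances (within 1e-9 nm, i.e. fp noise
    # on lattice models) so crystals cost O(#distinct distances) per q
    r <- rle(sort(round(d * 1e9)))
    d <- r$values * 1e-9
    w <- r$lengths
  }
  vapply(qGrid, function(q) 1 + (2 / n) * sum(w * sinc(q * d)), numeric(1))
}

#' Isotropic structure factor from a point model (Debye sum)
#'
#' Computes S(q) = (1/N) sum_i sum_j sinc(q r_ij) with sinc(0) = 1 (the
#' i = j self terms contribute 1 each, so S(0) = N and S -> 1 at large q).
#' Pair distances are taken without periodic wrapping: the model is a free
#' cluster. Above 2000 points the pair distances are histogrammed (bin
#' width 1e-3 nm) before the sinc sum; below, the sum is exact.
#'
#' Thermal averaging: when `nThermal > 1` (or a fluctuation spec is given),
#' `nThermal` configurations are generated by [thermalize()] — configuration
#' k uses seed `fluct@seed + k - 1` — and the S(q) curves are averaged.
#'
#' @param points a [PointSet-class].
#' @param qGrid ascending non-negative numeric (nm^-1).
#' @param nThermal number of thermal configurations to average (>= 1).
#' @param fluct a [FluctuationSpec-class]; required when `nThermal > 1`.
#' @return a [StructureFactorCurve-class].
#' @examples
#' cr <- buildCrystal(latticeFromConstants(3.5, 3.5, 3.5, repeats = c(3, 3, 3)))
#' sq <- sqFromModel(cr, seq(0, 5, 0.05))
#' sValues(sq)[1]  # S(0) = 27
#' @export
sqFromModel <- function(points, qGrid, nThermal = 1L, fluct = NULL) {
  stopifnot(is(points, "PointSet"))
  qGrid <- as.numeric(qGrid)
  if (is.unsorted(qGrid) || any(qGrid < 0))
    stop("q grid must be ascending and non-negative", call. = FALSE)
  nThermal <- as.integer(nThermal)
  if (nThermal > 1L && is.null(fluct))
    stop("nThermal > 1 requires a FluctuationSpec", call. = FALSE)
  n <- nPoints(points)
  freePoints <- pointSet(points@positions)   # drop box: free-cluster distances
  oneConfig <- function(p) {
    d <- as.numeric(stats::dist(p@positions))
    debyeFromDistances(d, n, qGrid, histogram = n > 2000L)
  }
  if (is.null(fluct)) {
    S <- oneConfig(freePoints)
  } else {
    S <- rep(0, length(qGrid))
    for (k in seq_len(nThermal)) {
      fk <- fluct
      fk@seed <- fluct@seed + k - 1L
      S <- S + oneConfig(thermalize(freePoints, fk))
    }
    S <- S / nThermal
  }
  structureFactorCurve(qGrid, S, n)
}

#' Structure factor from a solution intensity and a subunit form factor
#'
#' Inverts I(q) = N |f(q)|^2 S(q): S(q) = I(q) / (N |f(q)|^2). The result is
#' exact only for spherically symmetric subunits; for anisotropic subunits
#' (e.g. cylinders) systematic deviations from the true structure factor
#' appear and grow with q.
#'
#' @param intensity a [ScatteringCurve-class], the solution intensity.
#' @param formFactor a [ScatteringCurve-class] of <|f(q)|^2> on the same q
#'   grid (see [solutionFormFactor()]).
#' @param nSubunits the number of subunits N.
#' @return a [StructureFactorCurve-class].
#' @export
sqFromIntensity <- function(intensity, formFactor, nSubunits) {
  stopifnot(is(intensity, "ScatteringCurve"), is(formFactor, "ScatteringCurve"))
  if (length(intensity@q) != length(formFactor@q) ||
      any(abs(intensity@q - formFactor@q) > 1e-9))
    stop("intensity and form factor must share one q grid", call. = FALSE)
  bad <- which(formFactor@I <= 0)
  if (length(bad))
    stop(sprintf("form factor is not strictly positive at q = %.6g nm^-1",
                 intensity@q[bad[1]]), call. = FALSE)
  structureFactorCurve(intensity@q, intensity@I / (nSubunits * formFactor@I),
                       nSubunits)
}

# Shared sine-transform quadrature: returns sum_j w_j x_j sin(k_out r_j) for
# every output frequency, with Simpson or midpoint (dst) weights on a
# uniform abscissa grid.
sineQuadrature <- function(absc, x, freqs, method) {
  h <- absc[2] - absc[1]
  if (any(abs(diff(absc) - h) > 1e-9 * h))
    stop("grid must be uniform for the sine transform", call. = FALSE)
  if (method == "simpson") {
    n <- length(x)
    w <- rep(h / 3, n)
    if (n %% 2L == 1L) {
      w[seq(2L, n - 1L, by = 2L)] <- 4 * h / 3
      if (n > 3L) w[seq(3L, n - 2L, by = 2L)] <- 2 * h / 3
    } else {
      # even count: Simpson on the first n-1 points, trapezoid on the tail
      w <- rep(0, n)
      w[1:(n - 1L)] <- {
        wi <- rep(h / 3, n - 1L)
        wi[seq(2L, n - 2L, by = 2L)] <- 4 * h / 3
        if (n - 1L > 3L) wi[seq(3L, n - 3L, by = 2L)] <- 2 * h / 3
        wi
      }
      w[n - 1L] <- w[n - 1L] + h / 2
      w[n] <- h / 2
    }
  } else {
    w <- rep(h, length(x))    # midpoint rule: the discrete sine transform
  }
  sapply(freqs, function(k) sum(w * x * sin(k * absc)))
}

#' Structure factor from a radial distribution function
#'
#' Fourier sine transform of the pair correlations:
#' S(q) = 1 + (4 pi rho_b / q) integral_0^{r_max} r (g(r) - 1) sin(qr) dr,
#' truncated at the r_max of the input curve. `method = "simpson"` uses
#' composite Simpson quadrature on the stored grid (plus the analytically
#' vanishing [0, r_1] sliver by trapezoid); `method = "dst"` uses the
#' type-II discrete sine transform (midpoint weights on the uniform bin
#' centers) evaluated at its natural frequencies pi k / r_max and, when an
#' explicit `qGrid` is supplied, linearly interpolated onto it. At q = 0 the
#' analytic limit 1 + 4 pi rho_b integral r^2 (g - 1) dr is used.
#'
#' @param rdf an [RDFCurve-class].
#' @param qGrid output q grid (nm^-1); may be `NULL` for `method = "dst"`
#'   (natural frequencies are used).
#' @param method `"simpson"` or `"dst"`.
#' @return a [StructureFactorCurve-class] (`nSubunits` is carried as 1,
#'   since the transform knows only densities).
#' @export
sqFromGr <- function(rdf, qGrid = NULL, method = c("simpson", "dst")) {
  stopifnot(is(rdf, "RDFCurve"))
  method <- match.arg(method)
  r <- rdf@r
  x <- r * (rdf@g - 1)
  pref <- 4 * pi * rdf@rhoB
  sAt <- function(qs) {
    out <- numeric(length(qs))
    z <- qs == 0
    if (any(z))
      out[z] <- 1 + pref * simpsonUniform(r^2 * (rdf@g - 1), rdf@dr)
    if (any(!z)) {
      ints <- sineQuadrature(r, x, qs[!z], method)
      # [0, r_1] sliver: integrand vanishes at 0, trapezoid on the half bin
      if (method == "simpson")
        ints <- ints + sapply(qs[!z], function(q) r[1] / 2 * x[1] * sin(q * r[1]))
      out[!z] <- 1 + pref / qs[!z] * ints
    }
    out
  }
  if (method == "dst") {
    M <- length(r)
    qNat <- pi * seq_len(M) / rdf@rMax
    sNat <- sAt(qNat)
    if (is.null(qGrid)) return(structureFactorCurve(qNat, sNat, 1L))
    qGrid <- as.numeric(qGrid)
    sOut <- stats::approx(c(0, qNat), c(sAt(0), sNat), xout = qGrid,
                          rule = 2)$y
    return(structureFactorCurve(qGrid, sOut, 1L))
  }
  if (is.null(qGrid)) stop("qGrid is required for method = 'simpson'", call. = FALSE)
  structureFactorCurve(qGrid, sAt(as.numeric(qGrid)), 1L)
}
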