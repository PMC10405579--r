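# Pixel-center axis: (i + 1/2) * (2 qLimit / nPoints) - qLimit; even
# nPoints keeps every pixel off the exact q = 0 singularity.
pixelAxis <- function(nPoints, qLimit)
  (seq_len(nPoints) - 0.5) * (2 * qLimit / nPoints) - qLimit

# Flattened pixel table in column-major order of the nPoints x nPoints
# image (rows q_z, columns q_perp).
pixelTable <- function(nPoints, qLimit) {
  ax <- pixelAxis(nPoints, qLimit)
  qp <- rep(ax, each = nPoints)
  qz <- rep(ax, times = nPoints)
  q <- sqrt(qp^2 + qz^2)
  theta <- ifelse(q > 0, acos(pmin(1, pmax(-1, qz / pmax(q, 1e-300)))), 0)
  list(axis = ax, qPerp = qp, qZ = qz, q = q, theta = theta)
}

#' 2D single-orientation scattering pattern (Ewald-plane slice)
#'
#' Converts each detector pixel (q_perp, q_z) to polar reciprocal
#' coordinates q = (q_perp^2 + q_z^2)^(1/2), theta_q = arccos(q_z / q)
#' (theta_q = 0 at q = 0), interpolates the amplitude of the precomputed
#' grid at (q, theta_q, phi') — for negative q_perp at (q, theta_q,
#' phi' + pi) — and squares it. The flat detector is identified with the
#' (q_perp, q_z) plane (small-angle approximation, no Ewald curvature
#' correction). Pixels beyond the grid's q_max are zero-filled and flagged
#' in the image mask.
#'
#' @param grid a [ReciprocalGrid-class].
#' @param nPoints even number of pixels per axis.
#' @param qLimit half-range per axis (nm^-1).
#' @param phiPrime sampled azimuth (degrees, default 0).
#' @return a [DetectorImage-class] (rows: q_z ascending, columns: q_perp).
#' @export
singleOrientationPattern <- function(grid, nPoints, qLimit, phiPrime = 0) {
  stopifnot(is(grid, "ReciprocalGrid"))
  nPoints <- as.integer(nPoints)
  if (nPoints %% 2L != 0L)
    stop("nPoints must be even (center-pixel ambiguity)", call. = FALSE)
  px <- pixelTable(nPoints, qLimit)
  inRange <- px$q <= grid@qMax
  phi0 <- phiPrime * pi / 180
  phi <- ifelse(px$qPerp >= 0, phi0, phi0 + pi)
  vals <- numeric(length(px$q))
  if (any(inRange)) {
    st <- sin(px$theta[inRange])
    qvecs <- cbind(px$q[inRange] * st * cos(phi[inRange]),
                   px$q[inRange] * st * sin(phi[inRange]),
                   px$q[inRange] * cos(px$theta[inRange]))
    vals[inRange] <- Mod(interpolateAmplitude(grid, qvecs))^2
  }
  new("DetectorImage",
      values = matrix(vals, nPoints, nPoints),
      qPerp = px$axis, qZ = px$axis, qLimit = as.numeric(qLimit),
      phiPrime = as.numeric(phiPrime),
      mask = matrix(!inRange, nPoints, nPoints),
      metadata = list(mode = "single_orientation"))
}

#' 2D fiber diffraction pattern (azimuthal Monte Carlo average)
#'
#' For each pixel, averages |F(q, theta_q, phi)|^2 over azimuths phi drawn
#' uniformly from `phiDomain` (phi = phi_min + (phi_max - phi_min) u,
#' u ~ U[0, 1)); for negative q_perp the sampled azimuth is shifted by pi,
#' matching the single-orientation convention. The sample budget doubles
#' until the image-wide relative L2 change between consecutive estimates
#' drops below `relTol` or `maxSamples` is reached (non-convergence is
#' flagged in the metadata with a warning). Deterministic under `seed`.
#'
#' @param source a [ReciprocalGrid-class], [AssemblyNode-class] or
#'   [PointSet-class] (point scatterers).
#' @param nPoints even number of pixels per axis.
#' @param qLimit half-range per axis (nm^-1).
#' @param phiDomain azimuth sampling domain `[phi_min, phi_max)`, degrees.
#' @param relTol image-wide relative L2 convergence tolerance.
#' @param maxSamples maximal azimuth samples.
#' @param seed RNG seed.
#' @param nStart initial sample count (doubled each round).
#' @param ... passed to [amplitudeAt()].
#' @return a [DetectorImage-class] with `phiPrime = NA`.
#' @export
fiberPattern <- function(source, nPoints, qLimit, phiDomain = c(0, 360),
                         relTol = 1e-2, maxSamples = 2048L, seed = 1L,
                         nStart = 16L, ...) {
  nPoints <- as.integer(nPoints)
  if (nPoints %% 2L != 0L)
    stop("nPoints must be even (center-pixel ambiguity)", call. = FALSE)
  if (!(phiDomain[1] < phiDomain[2] && phiDomain[2] <= phiDomain[1] + 360))
    stop("phiDomain must satisfy phi_min < phi_max <= phi_min + 360", call. = FALSE)
  px <- pixelTable(nPoints, qLimit)
  inRange <- if (is(source, "ReciprocalGrid")) px$q <= source@qMax
             else rep(TRUE, length(px$q))
  st <- sin(px$theta[inRange])
  ct <- cos(px$theta[inRange])
  qSub <- px$q[inRange]
  shift <- ifelse(px$qPerp[inRange] >= 0, 0, pi)
  lo <- phiDomain[1] * pi / 180
  span <- (phiDomain[2] - phiDomain[1]) * pi / 180
  withSeed(seed, {
    total <- numeric(sum(inRange))
    nTot <- 0L
    est <- NULL
    converged <- FALSE
    batch <- as.integer(nStart)
    while (nTot < maxSamples) {
      for (k in seq_len(batch)) {
        phi <- lo + span * stats::runif(1) + shift
        qvecs <- cbind(qSub * st * cos(phi), qSub * st * sin(phi), qSub * ct)
        total <- total + Mod(amplitudeAt(source, qvecs, ...))^2
      }
      nTot <- nTot + batch
      newEst <- total / nTot
      if (!is.null(est)) {
        rel <- sqrt(sum((newEst - est)^2) / max(sum(newEst^2), 1e-300))
        if (rel < relTol) {
          est <- newEst
          converged <- TRUE
          break
        }
      }
      est <- newEst
      batch <- min(nTot, maxSamples - nTot)
      if (batch <= 0L) break
    }
    if (!converged)
      warning("fiber pattern did not converge within maxSamples")
    vals <- numeric(length(px$q))
    vals[inRange] <- est
    new("DetectorImage",
        values = matrix(vals, nPoints, nPoints),
        qPerp = px$axis, qZ = px$axis, qLimit = as.numeric(qLimit),
        phiPrime = NA_real_,
        mask = matrix(!inRange, nPoints, nPoints),
        metadata = list(mode = "fiber", nSamples = nTot, converged = converged,
                        seed = as.integer(seed), phiDomain = phiDomain))
  })
}

#' Export a detector image as 16-bit TIFF (display only)
#'
#' Linearly rescales the intensity matrix to [0, 1] and writes a 16-bit
#' grayscale TIFF. Cosmetic: the numeric contract lives in the image object
#' itself. Requires the `tiff` package.
#'
#' @param image a [DetectorImage-class].
#' @param path output file.
#' @param logScale take log1p of the intensities first.
#' @export
writeImageTIFF <- function(image, path, logScale = TRUE) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  v <- image@values
  if (logScale) v <- log1p(v)
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  # image rows run q_z ascending; TIFF rows run top-down
  tiff::writeTIFF(v[rev(seq_len(nrow(v))), ], path, bits.per.sample = 16L)
  invisible(path)
}
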