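# Deterministic polar layout: shell i carries 2i + 1 polar rows uniform in
# [0, pi]; non-pole rows carry 2(2i + 1) azimuths uniform in [0, 2pi); pole
# rows collapse to one sample; shell 0 is the origin node.
gridLayout <- function(qMax, nShells) {
  nShells <- as.integer(nShells)
  shellQ <- qMax * (0:nShells) / nShells
  shellTheta <- vector("list", nShells + 1L)
  rowNphi <- vector("list", nShells + 1L)
  rowOffset <- vector("list", nShells + 1L)
  off <- 1L
  for (i in 0:nShells) {
    if (i == 0L) {
      theta <- 0
      nphi <- 1L
    } else {
      nTheta <- 2L * i + 1L
      theta <- pi * (seq_len(nTheta) - 1L) / (nTheta - 1L)
      nphi <- ifelse(seq_len(nTheta) %in% c(1L, nTheta), 1L, 2L * nTheta)
    }
    shellTheta[[i + 1L]] <- theta
    rowNphi[[i + 1L]] <- as.integer(nphi)
    rowOffset[[i + 1L]] <- as.integer(off + cumsum(c(0L, nphi[-length(nphi)])))
    off <- off + sum(nphi)
  }
  list(shellQ = shellQ, shellTheta = shellTheta, rowNphi = rowNphi,
       rowOffset = rowOffset, nNodes = off - 1L)
}

# Cartesian coordinates of every node, in storage order.
gridNodeCoords <- function(layout) {
  qs <- thetas <- phis <- numeric(layout$nNodes)
  pos <- 1L
  for (i in seq_along(layout$shellTheta)) {
    q <- layout$shellQ[i]
    th <- layout$shellTheta[[i]]
    np <- layout$rowNphi[[i]]
    for (j in seq_along(th)) {
      ph <- 2 * pi * (seq_len(np[j]) - 1L) / np[j]
      idx <- pos:(pos + np[j] - 1L)
      qs[idx] <- q; thetas[idx] <- th[j]; phis[idx] <- ph
      pos <- pos + np[j]
    }
  }
  cbind(q = qs, theta = thetas, phi = phis)
}

polarToCartesian <- function(polar) {
  st <- sin(polar[, 2])
  cbind(polar[, 1] * st * cos(polar[, 3]),
        polar[, 1] * st * sin(polar[, 3]),
        polar[, 1] * cos(polar[, 2]))
}

#' Fill a polar reciprocal-space amplitude grid
#'
#' Evaluates an amplitude source (a [SubunitModel-class], a
#' [PointSet-class] of point scatterers, or an [AssemblyNode-class]) at
#' every node of the polar layout described in [ReciprocalGrid-class],
#' deterministically.
#'
#' @param source the amplitude source.
#' @param qMax maximal q (nm^-1).
#' @param nShells number of radial shells (uniform in q).
#' @param ... passed to [amplitudeAt()] (e.g. `scatteringLength` for point
#'   sets).
#' @return a [ReciprocalGrid-class].
#' @export
fillGrid <- function(source, qMax, nShells, ...) {
  if (qMax <= 0 || nShells < 1L) stop("qMax and nShells must be positive", call. = FALSE)
  lay <- gridLayout(qMax, nShells)
  qvecs <- polarToCartesian(gridNodeCoords(lay))
  # evaluate in chunks to bound the q x subunit working set
  chunk <- 65536L
  vals <- complex(length.out = nrow(qvecs))
  for (start in seq(1L, nrow(qvecs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(qvecs))
    vals[idx] <- amplitudeAt(source, qvecs[idx, , drop = FALSE], ...)
  }
  new("ReciprocalGrid", qMax = as.numeric(qMax), nShells = as.integer(nShells),
      shellQ = lay$shellQ, shellTheta = lay$shellTheta, rowNphi = lay$rowNphi,
      rowOffset = lay$rowOffset, values = vals)
}

# Bilinear angular interpolation within one shell, vectorized over
# (theta, phi); phi is periodic, pole rows are single samples.
evalShellAngular <- function(grid, shell, theta, phi) {
  if (shell == 0L) return(rep(grid@values[1], length(theta)))
  th <- grid@shellTheta[[shell + 1L]]
  np <- grid@rowNphi[[shell + 1L]]
  offs <- grid@rowOffset[[shell + 1L]]
  nTheta <- length(th)
  ht <- pi / (nTheta - 1L)
  j <- pmin(pmax(floor(theta / ht), 0), nTheta - 2L)
  tt <- theta / ht - j
  rowVal <- function(jj) {
    n <- np[jj + 1L]
    o <- offs[jj + 1L]
    out <- complex(length.out = length(jj))
    single <- n == 1L
    out[single] <- grid@values[o[single]]
    if (any(!single)) {
      ns <- n[!single]; os <- o[!single]
      hp <- 2 * pi / ns
      p <- phi[!single] %% (2 * pi)
      k <- floor(p / hp)
      u <- p / hp - k
      k <- k %% ns
      k2 <- (k + 1L) %% ns
      out[!single] <- (1 - u) * grid@values[os + k] + u * grid@values[os + k2]
    }
    out
  }
  (1 - tt) * rowVal(j) + tt * rowVal(j + 1L)
}

#' Interpolate a reciprocal grid at arbitrary q vectors
#'
#' Local interpolation in (q, theta, phi): Catmull-Rom cubic across radial
#' shells combined with bilinear interpolation in the angles within each
#' shell (periodic in phi, pole rows collapsed). Near q = 0 and q_max the
#' radial rule falls back to linear. Exact at grid nodes.
#'
#' @param grid a [ReciprocalGrid-class].
#' @param qvec a length-3 vector or n x 3 matrix (nm^-1); |q| must not
#'   exceed the grid's q_max.
#' @return complex vector of interpolated amplitudes.
#' @export
interpolateAmplitude <- function(grid, qvec) {
  qvec <- asQMatrix(qvec)
  q <- sqrt(rowSums(qvec^2))
  if (any(q > grid@qMax * (1 + 1e-9)))
    stop(sprintf("q = %.6g nm^-1 beyond the grid's q_max = %.6g",
                 max(q), grid@qMax), call. = FALSE)
  theta <- ifelse(q > 0, acos(pmin(1, pmax(-1, qvec[, 3] / pmax(q, 1e-300)))), 0)
  phi <- atan2(qvec[, 2], qvec[, 1]) %% (2 * pi)
  h <- grid@qMax / grid@nShells
  s <- pmin(pmax(floor(q / h), 0), grid@nShells - 1L)
  t <- q / h - s
  out <- complex(length.out = length(q))
  for (sv in unique(s)) {
    idx <- which(s == sv)
    thI <- theta[idx]; phI <- phi[idx]; tI <- t[idx]
    p1 <- evalShellAngular(grid, sv, thI, phI)
    p2 <- evalShellAngular(grid, sv + 1L, thI, phI)
    if (sv >= 1L && sv + 2L <= grid@nShells) {
      p0 <- evalShellAngular(grid, sv - 1L, thI, phI)
      p3 <- evalShellAngular(grid, sv + 2L, thI, phI)
      out[idx] <- 0.5 * (2 * p1 + (-p0 + p2) * tI +
                           (2 * p0 - 5 * p1 + 4 * p2 - p3) * tI^2 +
                           (-p0 + 3 * p1 - 3 * p2 + p3) * tI^3)
    } else {
      out[idx] <- (1 - tI) * p1 + tI * p2
    }
  }
  out
}

#' @rdname amplitudeAt
#' @export
setMethod("amplitudeAt", "ReciprocalGrid", function(object, qvec, ...)
  interpolateAmplitude(object, qvec))

sameLayout <- function(a, b) {
  isTRUE(all.equal(a@qMax, b@qMax)) && a@nShells == b@nShells &&
    length(a@values) == length(b@values)
}

#' Node-wise algebra on reciprocal grids
#'
#' `multiplyGrids` and `sumGrids` combine two grids with identical layouts
#' node by node (complex product / sum) — e.g. a structure-factor amplitude
#' grid times a form-factor grid gives the decorated-lattice amplitude.
#'
#' @param a,b [ReciprocalGrid-class] objects with identical layouts.
#' @return a [ReciprocalGrid-class].
#' @export
multiplyGrids <- function(a, b) {
  if (!sameLayout(a, b)) stop("grid layouts differ", call. = FALSE)
  initialize(a, values = a@values * b@values)
}

#' @rdname multiplyGrids
#' @export
sumGrids <- function(a, b) {
  if (!sameLayout(a, b)) stop("grid layouts differ", call. = FALSE)
  initialize(a, values = a@values + b@values)
}

#' Monte Carlo orientation average of an amplitude source
#'
#' Estimates I(q) = < |F(q, Omega)|^2 > over the reciprocal-space solid
#' angle by uniform direction sampling (area-preserving map phi = 2 pi u,
#' cos theta = 2 v - 1). The sample budget doubles until the relative L2
#' change of the whole curve between consecutive estimates drops below
#' `relTol` or `maxSamples` is reached; non-convergence sets
#' `metadata$converged = FALSE` (with a warning) rather than failing.
#'
#' @param source a [ReciprocalGrid-class], [AssemblyNode-class],
#'   [SubunitModel-class] or [PointSet-class].
#' @param qGrid ascending non-negative q magnitudes (nm^-1).
#' @param relTol relative L2 convergence tolerance.
#' @param maxSamples maximal number of direction samples.
#' @param seed RNG seed.
#' @param nStart initial direction count (doubled each round).
#' @param ... passed to [amplitudeAt()].
#' @return a [ScatteringCurve-class]; metadata records `nSamples`,
#'   `converged` and the seed.
#' @export
orientationAverage <- function(source, qGrid, relTol = 1e-3,
                               maxSamples = 2^16, seed = 1L, nStart = 256L, ...) {
  if (relTol <= 0) stop("relTol must be positive", call. = FALSE)
  qGrid <- as.numeric(qGrid)
  withSeed(seed, {
    total <- rep(0, length(qGrid))
    nTot <- 0L
    est <- NULL
    converged <- FALSE
    batch <- as.integer(nStart)
    while (nTot < maxSamples) {
      done <- 0L
      while (done < batch) {
        m <- min(4096L, batch - done)   # keep the q x direction block small
        dirs <- randomDirections(m)
        qvecs <- dirs[rep(seq_len(m), times = length(qGrid)), , drop = FALSE] *
          rep(qGrid, each = m)
        amp <- amplitudeAt(source, qvecs, ...)
        total <- total + colSums(matrix(Mod(amp)^2, nrow = m))
        done <- done + m
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
      warning("orientation average did not converge within maxSamples")
    scatteringCurve(qGrid, pmax(est, 0),
                    metadata = list(nSamples = nTot, converged = converged,
                                    seed = as.integer(seed)))
  })
}
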