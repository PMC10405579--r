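# Volume of the intersection of a ball of radius `a` centered at distance
# `d` from the origin with the origin-centered ball of radius `R`;
# vectorized over d.
sphereBallOverlap <- function(R, a, d) {
  out <- numeric(length(d))
  vball <- 4 / 3 * pi * a^3
  full <- d <= R - a
  out[full] <- vball
  lens <- !full & d < R + a & d > abs(R - a)
  dl <- d[lens]
  out[lens] <- pi * (R + a - dl)^2 *
    (dl^2 + 2 * dl * a - 3 * a^2 + 2 * dl * R + 6 * a * R - 3 * R^2) / (12 * dl)
  inside <- !full & d <= a - R     # reference ball swallowed by the subunit
  out[inside] <- 4 / 3 * pi * R^3
  out
}

#' Radial distribution function from a point model
#'
#' Computes g(r) = N(r) / (4 pi r^2 dr rho_b) by shell binning of
#' minimum-image pair distances, where N(r) is the count of subunits in the
#' half-open shell [r, r + dr) around a reference subunit, averaged over
#' `nRefs` references (all subunits by default — deterministic) and over
#' `nConfigs` thermalized configurations. The bulk density rho_b = N / V
#' comes from the periodic box, which is therefore required. When
#' `subunitRadius > 0`, each subunit contributes to every bin the fraction
#' of its spherical volume lying inside that shell instead of a unit count.
#'
#' @param points a [PointSet-class] with a periodic box.
#' @param dr bin width (nm).
#' @param rMax outer radius (nm); must not exceed half the smallest box edge.
#' @param subunitRadius subunit radius (nm), 0 for point subunits.
#' @param nConfigs number of thermal configurations (>= 1).
#' @param nRefs number of reference subunits; >= N means all (deterministic).
#' @param fluct a [FluctuationSpec-class], required when `nConfigs > 1`.
#' @param seed seed for the reference-subunit selection when `nRefs < N`.
#' @return an [RDFCurve-class] with bin centers at dr/2 + k dr.
#' @examples
#' cr <- buildCrystal(latticeFromConstants(3.5, 3.5, 3.5, repeats = c(5, 5, 5)))
#' g <- grFromModel(cr, dr = 0.05, rMax = 8)
#' rValues(g)[which.max(gValues(g))]  # first coordination shell near 3.5 nm
#' @export
grFromModel <- function(points, dr, rMax, subunitRadius = 0, nConfigs = 1L,
                        nRefs = Inf, fluct = NULL, seed = 1L) {
  stopifnot(is(points, "PointSet"), dr > 0)
  box <- points@box
  if (is.null(box))
    stop("grFromModel needs a periodic box (rho_b is undefined without one)",
         call. = FALSE)
  if (rMax > min(box) / 2 + 1e-9)
    stop("rMax must not exceed half the smallest box edge", call. = FALSE)
  nConfigs <- as.integer(nConfigs)
  if (nConfigs > 1L && is.null(fluct))
    stop("nConfigs > 1 requires a FluctuationSpec", call. = FALSE)
  n <- nPoints(points)
  rhoB <- n / prod(box)
  nBins <- floor(rMax / dr + 1e-9)
  edges <- dr * (0:nBins)
  centers <- edges[-1] - dr / 2
  refs <- if (nRefs >= n) seq_len(n) else
    withSeed(seed, sample.int(n, as.integer(nRefs)))
  accum <- numeric(nBins)
  for (cfg in seq_len(nConfigs)) {
    p <- points
    if (!is.null(fluct)) {
      fk <- fluct
      fk@seed <- fluct@seed + cfg - 1L
      p <- thermalize(points, fk)
    }
    pos <- p@positions
    for (i in refs) {
      d <- distancesFrom(pos, i, box)
      if (subunitRadius <= 0) {
        k <- floor(d / dr) + 1L
        k <- k[k >= 1L & k <= nBins]
        accum <- accum + tabulate(k, nbins = nBins)
      } else {
        d <- d[d - subunitRadius < rMax]
        cum <- vapply(edges, function(e) sum(sphereBallOverlap(e, subunitRadius, d)),
                      numeric(1))
        accum <- accum + diff(cum) / (4 / 3 * pi * subunitRadius^3)
      }
    }
  }
  counts <- accum / (length(refs) * nConfigs)
  g <- counts / (4 * pi * centers^2 * dr * rhoB)
  rdfCurve(centers, g, rhoB, dr = dr, rMax = nBins * dr)
}

#' Radial distribution function from a structure factor
#'
#' Inverse sine transform of the excess structure factor:
#' g(r) = 1 + 1 / (2 pi^2 rho_b r) integral_0^{q_max} q (S(q) - 1) sin(qr) dq,
#' truncated at `qMax`. `method = "simpson"` integrates on the stored q grid
#' with composite Simpson weights and requires an explicit uniform `rGrid`;
#' `method = "dst"` applies the discrete sine transform (midpoint weights)
#' and returns g on the natural radii pi k / q_edge unless an `rGrid` is
#' given (then linear interpolation onto it). Truncation at finite qMax
#' makes the result oscillate, possibly below zero, near sharp features.
#'
#' @param sq a [StructureFactorCurve-class] on a uniform q grid covering
#'   `[0, qMax]` (a leading q = 0 node is allowed and ignored).
#' @param rhoB bulk subunit number density (nm^-3).
#' @param rGrid output radii (nm, uniform ascending, excluding 0); `NULL`
#'   allowed for `method = "dst"`.
#' @param qMax integration cutoff (nm^-1).
#' @param method `"simpson"` or `"dst"`.
#' @return an [RDFCurve-class].
#' @export
grFromSq <- function(sq, rhoB, rGrid = NULL, qMax = max(qValues(sq)),
                     method = c("simpson", "dst")) {
  stopifnot(is(sq, "StructureFactorCurve"))
  method <- match.arg(method)
  if (rhoB <= 0) stop("rhoB must be positive", call. = FALSE)
  keep <- sq@q <= qMax + 1e-9 & sq@q > 0
  qs <- sq@q[keep]
  x <- qs * (sq@S[keep] - 1)
  h <- qs[2] - qs[1]
  gAt <- function(rs) {
    ints <- sineQuadrature(qs, x, rs, method)
    if (method == "simpson")
      ints <- ints + sapply(rs, function(r) qs[1] / 2 * x[1] * sin(qs[1] * r))
    1 + ints / (2 * pi^2 * rhoB * rs)
  }
  if (method == "dst") {
    M <- length(qs)
    qEdge <- qs[M] + h / 2
    rNat <- pi * seq_len(M) / qEdge
    gNat <- gAt(rNat)
    if (is.null(rGrid))
      return(rdfCurve(rNat, gNat, rhoB, dr = rNat[1], rMax = rNat[M] + rNat[1] / 2))
    rGrid <- as.numeric(rGrid)
    if (any(rGrid <= 0)) stop("r = 0 must be excluded from the grid", call. = FALSE)
    gOut <- stats::approx(rNat, gNat, xout = rGrid, rule = 2)$y
    return(rdfCurve(rGrid, gOut, rhoB))
  }
  if (is.null(rGrid)) stop("rGrid is required for method = 'simpson'", call. = FALSE)
  rGrid <- as.numeric(rGrid)
  if (any(rGrid <= 0)) stop("r = 0 must be excluded from the grid", call. = FALSE)
  rdfCurve(rGrid, gAt(rGrid), rhoB)
}

#' Coordination number over a radial window
#'
#' Integrates 4 pi rho_b integral_{r1}^{r2} r^2 g(r) dr — the number of
#' neighbors in the shell [r1, r2] — by Simpson quadrature on a refined
#' uniform grid with g linearly interpolated from the stored bins.
#'
#' @param rdf an [RDFCurve-class].
#' @param r1,r2 window bounds (nm), r1 < r2 <= r_max.
#' @param nQuad number of quadrature points (made odd internally).
#' @return the coordination number (dimensionless).
#' @examples
#' # uniform density: closed-form (4 pi / 3) rho (r2^3 - r1^3)
#' flat <- rdfCurve(seq(0.05, 10, 0.1), rep(1, 100), rhoB = 0.02)
#' coordinationNumber(flat, 2, 3)
#' @export
coordinationNumber <- function(rdf, r1, r2, nQuad = 401L) {
  stopifnot(is(rdf, "RDFCurve"))
  if (!(r1 < r2)) stop("r1 must be smaller than r2", call. = FALSE)
  if (r2 > rdf@rMax + 1e-9 || r1 < 0)
    stop("window out of the curve's range", call. = FALSE)
  nQuad <- as.integer(nQuad)
  if (nQuad %% 2L == 0L) nQuad <- nQuad + 1L
  rr <- seq(r1, r2, length.out = nQuad)
  gg <- stats::approx(rdf@r, rdf@g, xout = rr, rule = 2)$y
  4 * pi * rdf@rhoB * simpsonUniform(rr^2 * gg, rr[2] - rr[1])
}
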