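#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Docking list of subunit positions
#'
#' A `PointSet` is an ordered list of subunit positions in nanometres — the
#' "docking list" (dol) that places copies of a repeating subunit in an
#' assembly. Each point may optionally carry a Tait-Bryan orientation triple
#' (degrees) and the set may carry a periodic box (cell edge lengths, nm)
#' used for minimum-image distances.
#'
#' @slot positions numeric matrix, n x 3, coordinates in nm.
#' @slot orientations numeric matrix, n x 3 Tait-Bryan angles (alpha, beta,
#'   gamma) in degrees, or `NULL` when the points carry no orientation.
#' @slot box numeric of length 3 (periodic cell edges, nm) or `NULL` for a
#'   free (non-periodic) cluster.
#' @exportClass PointSet
setClass("PointSet",
  representation(positions = "matrix", orientations = "matrixOrNULL",
                 box = "numericOrNULL"),
  validity = function(object) {
    p <- object@positions
    if (!is.numeric(p) || ncol(p) != 3L) return("positions must be an n x 3 numeric matrix")
    if (nrow(p) < 1L) return("positions must be non-empty")
    if (!all(is.finite(p))) return("all coordinates must be finite")
    o <- object@orientations
    if (!is.null(o)) {
      if (!is.numeric(o) || ncol(o) != 3L) return("orientations must be an n x 3 numeric matrix")
      if (nrow(o) != nrow(p)) return("orientations must have one row per position")
      if (!all(is.finite(o))) return("orientations must be finite")
    }
    b <- object@box
    if (!is.null(b)) {
      if (length(b) != 3L || !all(is.finite(b)) || any(b <= 0))
        return("box must be 3 positive finite edge lengths (nm)")
    }
    TRUE
  })

#' Construct a PointSet
#'
#' @param positions n x 3 numeric matrix of coordinates (nm), or a length-3
#'   vector for a single point.
#' @param orientations optional n x 3 matrix of Tait-Bryan angles (degrees).
#' @param box optional length-3 positive numeric, periodic cell edges (nm).
#' @return A [PointSet-class] object.
#' @export
pointSet <- function(positions, orientations = NULL, box = NULL) {
  if (is.vector(positions) && length(positions) == 3L)
    positions <- matrix(positions, nrow = 1L)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (!is.null(orientations)) {
    orientations <- as.matrix(orientations)
    storage.mode(orientations) <- "double"
    dimnames(orientations) <- NULL
  }
  if (!is.null(box)) box <- as.numeric(box)
  new("PointSet", positions = positions, orientations = orientations, box = box)
}

#' @describeIn pointSet Number of points.
#' @param x,object a `PointSet`.
#' @export
nPoints <- function(x) nrow(x@positions)

#' Accessors for PointSet slots
#'
#' @param x a [PointSet-class].
#' @return `positions()` the n x 3 coordinate matrix; `orientations()` the
#'   angle matrix or `NULL`; `boxEdges()` the periodic box or `NULL`.
#' @export
positions <- function(x) x@positions

#' @rdname positions
#' @export
orientations <- function(x) x@orientations

#' @rdname positions
#' @export
boxEdges <- function(x) x@box

setMethod("show", "PointSet", function(object) {
  cat(sprintf("PointSet with %d point(s)%s%s\n", nPoints(object),
              if (!is.null(object@orientations)) ", oriented" else "",
              if (!is.null(object@box))
                sprintf(", periodic box %.4g x %.4g x %.4g nm",
                        object@box[1], object@box[2], object@box[3]) else ""))
  n <- min(3L, nPoints(object))
  for (i in seq_len(n))
    cat(sprintf("  [%d] %10.4f %10.4f %10.4f\n", i, object@positions[i, 1],
                object@positions[i, 2], object@positions[i, 3]))
  if (nPoints(object) > n) cat("  ...\n")
})

#' Lattice specification
#'
#' Defines a Bravais lattice either by three lattice vectors (nm) or by
#' lattice constants a, b, c (nm) and angles alpha, beta, gamma (degrees),
#' plus the number of translational repeats along each direction.
#'
#' @slot vectors 3 x 3 numeric matrix, rows are the lattice vectors a, b, c (nm).
#' @slot repeats integer of length 3, repeats along a, b, c (>= 1).
#' @exportClass LatticeSpec
setClass("LatticeSpec",
  representation(vectors = "matrix", repeats = "integer"),
  validity = function(object) {
    v <- object@vectors
    if (!is.numeric(v) || any(dim(v) != c(3L, 3L))) return("vectors must be a 3 x 3 matrix")
    if (!all(is.finite(v))) return("lattice vectors must be finite")
    if (any(sqrt(rowSums(v^2)) <= 0)) return("lattice vector lengths must be strictly positive")
    if (abs(det(v)) < 1e-12 * prod(sqrt(rowSums(v^2))))
      return("lattice vectors are degenerate (coplanar)")
    r <- object@repeats
    if (length(r) != 3L || any(r < 1L)) return("repeats must be three integers >= 1")
    TRUE
  })

#' @rdname latticeSpec
#' @param object a `LatticeSpec`.
#' @export
latticeVectors <- function(object) object@vectors

#' @rdname latticeSpec
#' @export
latticeRepeats <- function(object) object@repeats

setMethod("show", "LatticeSpec", function(object) {
  cat("LatticeSpec\n  vectors (nm):\n")
  for (i in 1:3) cat(sprintf("    %10.4f %10.4f %10.4f\n",
      object@vectors[i, 1], object@vectors[i, 2], object@vectors[i, 3]))
  cat(sprintf("  repeats: %d x %d x %d\n", object@repeats[1],
              object@repeats[2], object@repeats[3]))
})

#' Random fluctuation specification
#'
#' Parameters of the random displacements added by [thermalize()]: either
#' uniform per-coordinate fluctuations Delta r = 2 u v - u with v ~ U[0, 1),
#' or zero-mean Gaussian displacements of standard deviation `sigmaU`.
#'
#' @slot kind `"uniform"` or `"gaussian"`.
#' @slot u length-3 non-negative numeric, maximal fluctuation per coordinate (nm).
#' @slot sigmaU non-negative numeric, Gaussian standard deviation (nm).
#' @slot seed integer seed.
#' @exportClass FluctuationSpec
setClass("FluctuationSpec",
  representation(kind = "character", u = "numeric", sigmaU = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("uniform", "gaussian")) return("kind must be 'uniform' or 'gaussian'")
    if (length(object@u) != 3L || any(object@u < 0)) return("u components must be >= 0")
    if (length(object@sigmaU) != 1L || object@sigmaU < 0) return("sigmaU must be >= 0")
    TRUE
  })

#' @rdname FluctuationSpec-class
#' @param kind `"uniform"` or `"gaussian"`.
#' @param u maximal fluctuation per coordinate (nm); scalar is recycled.
#' @param sigmaU Gaussian standard deviation (nm).
#' @param seed integer seed used when the spec is applied.
#' @export
fluctuationSpec <- function(kind = c("uniform", "gaussian"), u = c(0, 0, 0),
                            sigmaU = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (length(u) == 1L) u <- rep(u, 3L)
  new("FluctuationSpec", kind = kind, u = as.numeric(u),
      sigmaU = as.numeric(sigmaU), seed = as.integer(seed))
}

#' Metropolis Monte Carlo configuration
#'
#' Parameters of [mcSimulate()]: the pair potential acting between static
#' nearest neighbors (harmonic or Lennard-Jones), the thermal energy kBT in
#' the same energy units as the potential, the proposal step size, the
#' neighbor cutoff used once on the initial configuration, and the seed.
#'
#' @slot potential `"harmonic"` or `"lennard_jones"`.
#' @slot kSpring,r0Spring harmonic stiffness (energy nm^-2) and rest length (nm).
#' @slot epsilon,sigmaLJ Lennard-Jones well depth (energy) and length (nm).
#' @slot kBT thermal energy.
#' @slot maxIterations number of Metropolis iterations.
#' @slot maxStep half-width of the uniform displacement proposal (nm).
#' @slot neighborCutoff distance cutoff selecting nearest neighbors (nm).
#' @slot seed integer seed.
#' @exportClass MCConfig
setClass("MCConfig",
  representation(potential = "character", kSpring = "numeric", r0Spring = "numeric",
                 epsilon = "numeric", sigmaLJ = "numeric", kBT = "numeric",
                 maxIterations = "integer", maxStep = "numeric",
                 neighborCutoff = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@potential %in% c("harmonic", "lennard_jones"))
      return("potential must be 'harmonic' or 'lennard_jones'")
    for (nm in c("kSpring", "r0Spring", "epsilon", "sigmaLJ", "kBT",
                 "maxStep", "neighborCutoff")) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        return(sprintf("%s must be a single positive finite number", nm))
    }
    if (object@maxIterations < 0L) return("maxIterations must be >= 0")
    TRUE
  })

#' @rdname MCConfig-class
#' @param potential,kSpring,r0Spring,epsilon,sigmaLJ,kBT,maxIterations,maxStep,neighborCutoff,seed
#'   see the class slots.
#' @export
mcConfig <- function(potential = c("harmonic", "lennard_jones"), kSpring = 1,
                     r0Spring = 1, epsilon = 1, sigmaLJ = 1, kBT = 1,
                     maxIterations = 1000L, maxStep = 0.1,
                     neighborCutoff = 1.5, seed = 1L) {
  potential <- match.arg(potential)
  new("MCConfig", potential = potential, kSpring = as.numeric(kSpring),
      r0Spring = as.numeric(r0Spring), epsilon = as.numeric(epsilon),
      sigmaLJ = as.numeric(sigmaLJ), kBT = as.numeric(kBT),
      maxIterations = as.integer(maxIterations), maxStep = as.numeric(maxStep),
      neighborCutoff = as.numeric(neighborCutoff), seed = as.integer(seed))
}

#' Geometric subunit model
#'
#' A scattering subunit with a closed-form amplitude: a homogeneous sphere,
#' a homogeneous cylinder (axis along the local z), or a point scatterer.
#' Sphere and cylinder carry an electron-density contrast (e nm^-3); the
#' point scatterer carries a scattering length (electrons). Amplitudes are
#' reported in electron units; the Thomson-length prefactor r0^2 of the
#' absolute intensity scale is a documented constant multiplier
#' ([thomsonLength]) and is not folded into the curves.
#'
#' @slot kind `"sphere"`, `"cylinder"` or `"point"`.
#' @slot radius sphere/cylinder radius (nm).
#' @slot height cylinder height (nm).
#' @slot contrast electron-density contrast (e nm^-3).
#' @slot scatteringLength point scattering length (electrons).
#' @exportClass SubunitModel
setClass("SubunitModel",
  representation(kind = "character", radius = "numeric", height = "numeric",
                 contrast = "numeric", scatteringLength = "numeric"),
  validity = function(object) {
    k <- object@kind
    if (!k %in% c("sphere", "cylinder", "point")) return("unknown subunit kind")
    if (k %in% c("sphere", "cylinder") &&
        (length(object@radius) != 1L || object@radius <= 0))
      return("radius must be positive")
    if (k == "cylinder" && (length(object@height) != 1L || object@height <= 0))
      return("height must be positive")
    TRUE
  })

#' @rdname SubunitModel-class
#' @param radius sphere radius (nm).
#' @param contrast electron-density contrast (e nm^-3).
#' @export
sphereModel <- function(radius, contrast = 1)
  new("SubunitModel", kind = "sphere", radius = as.numeric(radius),
      height = NA_real_, contrast = as.numeric(contrast),
      scatteringLength = NA_real_)

#' @rdname SubunitModel-class
#' @param height cylinder height (nm); axis along local z.
#' @export
cylinderModel <- function(radius, height, contrast = 1)
  new("SubunitModel", kind = "cylinder", radius = as.numeric(radius),
      height = as.numeric(height), contrast = as.numeric(contrast),
      scatteringLength = NA_real_)

#' @rdname SubunitModel-class
#' @param scatteringLength scattering length (electrons).
#' @export
pointScatterer <- function(scatteringLength = 1)
  new("SubunitModel", kind = "point", radius = NA_real_, height = NA_real_,
      contrast = NA_real_, scatteringLength = as.numeric(scatteringLength))

#' Subunit volume (nm^3)
#'
#' @param model a [SubunitModel-class] with spatial extent (sphere or cylinder).
#' @return the geometric volume in nm^3.
#' @export
subunitVolume <- function(model) {
  switch(model@kind,
    sphere = 4 / 3 * pi * model@radius^3,
    cylinder = pi * model@radius^2 * model@height,
    stop("point scatterers have no volume"))
}

setMethod("show", "SubunitModel", function(object) {
  cat(switch(object@kind,
    sphere = sprintf("SubunitModel: sphere, R = %.4g nm, contrast = %.4g e nm^-3\n",
                     object@radius, object@contrast),
    cylinder = sprintf("SubunitModel: cylinder, R = %.4g nm, H = %.4g nm, contrast = %.4g e nm^-3\n",
                       object@radius, object@height, object@contrast),
    point = sprintf("SubunitModel: point scatterer, b = %.4g e\n",
                    object@scatteringLength)))
})

#' Thomson scattering length (classical electron radius), in nm
#'
#' 2.82e-5 Angstrom = 2.82e-6 nm; the absolute per-electron amplitude scale
#' of X-ray scattering. Curves produced by this package are in electron
#' units; multiply intensities by `thomsonLength^2` for absolute scale.
#' @export
thomsonLength <- 2.82e-6

#' One-dimensional scattering curve
#'
#' Intensity I(q) sampled on an ascending non-negative q grid (nm^-1).
#' `metadata` records provenance (seed, convergence flags, sample counts).
#'
#' @slot q ascending non-negative numeric, nm^-1.
#' @slot I non-negative numeric of the same length (electron units).
#' @slot metadata list of provenance entries.
#' @exportClass ScatteringCurve
setClass("ScatteringCurve",
  representation(q = "numeric", I = "numeric", metadata = "list"),
  validity = function(object) {
    if (length(object@q) != length(object@I)) return("q and I must have equal length")
    if (length(object@q) < 1L) return("curve must be non-empty")
    if (any(!is.finite(object@q)) || any(!is.finite(object@I))) return("values must be finite")
    if (any(object@q < 0)) return("q must be non-negative")
    if (is.unsorted(object@q, strictly = TRUE)) return("q must be strictly ascending")
    TRUE
  })

#' @rdname ScatteringCurve-class
#' @param q,I grid and intensity values.
#' @param metadata list of provenance entries.
#' @export
scatteringCurve <- function(q, I, metadata = list())
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I), metadata = metadata)

#' Accessors for 1D curves
#' @param x a curve object.
#' @export
qValues <- function(x) x@q

#' @rdname qValues
#' @export
intensities <- function(x) x@I

#' @rdname qValues
#' @export
curveMetadata <- function(x) x@metadata

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d points, q in [%.4g, %.4g] nm^-1\n",
              length(object@q), min(object@q), max(object@q)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Structure-factor curve
#'
#' S(q) of an N-subunit arrangement on an ascending q grid. Produced by the
#' Debye sum (S(0) = N, S -> 1 at large q), by inversion of an intensity, or
#' by the sine transform of g(r).
#'
#' @slot q ascending non-negative numeric, nm^-1.
#' @slot S numeric of the same length.
#' @slot nSubunits positive integer N.
#' @exportClass StructureFactorCurve
setClass("StructureFactorCurve",
  representation(q = "numeric", S = "numeric", nSubunits = "integer"),
  validity = function(object) {
    if (length(object@q) != length(object@S)) return("q and S must have equal length")
    if (any(!is.finite(object@S))) return("S must be finite")
    if (any(object@q < 0)) return("q must be non-negative")
    if (is.unsorted(object@q, strictly = TRUE)) return("q must be strictly ascending")
    if (object@nSubunits < 1L) return("nSubunits must be >= 1")
    TRUE
  })

#' @rdname StructureFactorCurve-class
#' @param q,S grid and structure-factor values.
#' @param nSubunits number of subunits N.
#' @export
structureFactorCurve <- function(q, S, nSubunits)
  new("StructureFactorCurve", q = as.numeric(q), S = as.numeric(S),
      nSubunits = as.integer(nSubunits))

#' @rdname qValues
#' @export
sValues <- function(x) x@S

#' @rdname qValues
#' @export
nSubunits <- function(x) x@nSubunits

setMethod("show", "StructureFactorCurve", function(object) {
  cat(sprintf("StructureFactorCurve: N = %d, %d points, q in [%.4g, %.4g] nm^-1\n",
              object@nSubunits, length(object@q), min(object@q), max(object@q)))
})

#' Radial distribution function curve
#'
#' g(r) on uniform bins of width `dr` (bin centers stored), together with
#' the bulk subunit number density rho_b (nm^-3) used for normalization and
#' for coordination-number integrals.
#'
#' @slot r bin centers, uniform ascending positive numeric (nm).
#' @slot g g(r) values (may dip below zero for transform-derived curves).
#' @slot rhoB bulk number density (nm^-3).
#' @slot dr bin width (nm).
#' @slot rMax outer edge of the last bin (nm).
#' @exportClass RDFCurve
setClass("RDFCurve",
  representation(r = "numeric", g = "numeric", rhoB = "numeric",
                 dr = "numeric", rMax = "numeric"),
  validity = function(object) {
    if (length(object@r) != length(object@g)) return("r and g must have equal length")
    if (length(object@r) < 2L) return("need at least two bins")
    if (any(object@r <= 0)) return("r must be positive")
    dd <- diff(object@r)
    if (any(abs(dd - object@dr) > 1e-9 * object@dr)) return("r grid must be uniform with spacing dr")
    if (object@rhoB <= 0) return("rhoB must be positive")
    if (any(!is.finite(object@g))) return("g must be finite")
    TRUE
  })

#' @rdname RDFCurve-class
#' @param r,g bin centers (nm) and g(r) values.
#' @param rhoB bulk number density (nm^-3).
#' @param dr bin width (nm); defaults to the grid spacing.
#' @param rMax outer edge of the last bin (nm).
#' @export
rdfCurve <- function(r, g, rhoB, dr = NULL, rMax = NULL) {
  r <- as.numeric(r)
  if (is.null(dr)) dr <- r[2] - r[1]
  if (is.null(rMax)) rMax <- r[length(r)] + dr / 2
  new("RDFCurve", r = r, g = as.numeric(g), rhoB = as.numeric(rhoB),
      dr = as.numeric(dr), rMax = as.numeric(rMax))
}

#' @rdname qValues
#' @export
rValues <- function(x) x@r

#' @rdname qValues
#' @export
gValues <- function(x) x@g

#' @rdname qValues
#' @export
bulkDensity <- function(x) x@rhoB

setMethod("show", "RDFCurve", function(object) {
  cat(sprintf("RDFCurve: %d bins, dr = %.4g nm, r_max = %.4g nm, rho_b = %.6g nm^-3\n",
              length(object@r), object@dr, object@rMax, object@rhoB))
})

#' Polar reciprocal-space amplitude grid
#'
#' Complex scattering amplitudes F(q, theta_q, phi_q) sampled on radial
#' shells uniform in q up to `qMax`. Shell i (i = 1..nShells) carries
#' 2i + 1 polar samples uniform in [0, pi]; each non-pole polar row carries
#' 2(2i + 1) azimuthal samples uniform in [0, 2pi); pole rows collapse to a
#' single sample. Shell 0 is the single origin node.
#'
#' @slot qMax maximal q (nm^-1).
#' @slot nShells number of radial shells.
#' @slot shellQ q of every shell (length nShells + 1, starting at 0).
#' @slot shellTheta list: polar angles per shell.
#' @slot rowNphi list: azimuthal sample count per polar row, per shell.
#' @slot rowOffset list: 1-based start index of each polar row in `values`.
#' @slot values complex vector of amplitudes, rows concatenated.
#' @exportClass ReciprocalGrid
setClass("ReciprocalGrid",
  representation(qMax = "numeric", nShells = "integer", shellQ = "numeric",
                 shellTheta = "list", rowNphi = "list", rowOffset = "list",
                 values = "complex"),
  validity = function(object) {
    if (object@qMax <= 0) return("qMax must be positive")
    if (object@nShells < 1L) return("nShells must be >= 1")
    if (length(object@shellQ) != object@nShells + 1L) return("shellQ length mismatch")
    if (is.unsorted(object@shellQ, strictly = TRUE)) return("shellQ must ascend")
    if (max(object@shellQ) > object@qMax + 1e-12) return("shellQ exceeds qMax")
    n <- sum(vapply(object@rowNphi, sum, numeric(1)))
    if (n != length(object@values)) return("value count does not match layout")
    TRUE
  })

#' @rdname qValues
#' @export
gridQMax <- function(x) x@qMax

#' @rdname qValues
#' @export
gridNShells <- function(x) x@nShells

setMethod("show", "ReciprocalGrid", function(object) {
  cat(sprintf("ReciprocalGrid: q_max = %.4g nm^-1, %d shells, %d nodes\n",
              object@qMax, object@nShells, length(object@values)))
})

#' Hierarchical assembly of scattering subunits
#'
#' A tree node combining child amplitude sources into one structure. Each
#' child (a [SubunitModel-class], a [PointSet-class] of point scatterers, a
#' [ReciprocalGrid-class], or another `AssemblyNode`) is placed one or more
#' times; a placement is a Tait-Bryan rotation (alpha, beta, gamma, degrees;
#' intrinsic rotations about x, then y, then z) followed by a translation
#' (nm). The node amplitude is the sum over children and placements of the
#' rotated child amplitude times the translation phase factor.
#'
#' @slot children list of amplitude sources.
#' @slot placements list (parallel to `children`) of numeric matrices with
#'   columns alpha, beta, gamma, x, y, z — one row per placed copy.
#' @exportClass AssemblyNode
setClass("AssemblyNode",
  representation(children = "list", placements = "list"),
  validity = function(object) {
    if (length(object@children) == 0L) return("assembly needs at least one child")
    if (length(object@placements) != length(object@children))
      return("placements must parallel children")
    for (p in object@placements) {
      if (!is.matrix(p) || ncol(p) != 6L || nrow(p) < 1L)
        return("each placement matrix needs columns alpha,beta,gamma,x,y,z and >= 1 row")
    }
    ok <- vapply(object@children, function(ch)
      is(ch, "SubunitModel") || is(ch, "PointSet") || is(ch, "ReciprocalGrid") ||
        is(ch, "AssemblyNode"), logical(1))
    if (!all(ok)) return("unsupported child type")
    TRUE
  })

#' @rdname AssemblyNode-class
#' @param children list of amplitude sources (or a single source).
#' @param placements a single placement matrix shared syntax: either one
#'   matrix applied to a single child, or a list parallel to `children`.
#'   Columns: alpha, beta, gamma (degrees), x, y, z (nm). A `NULL` placement
#'   means one identity placement.
#' @export
assemblyNode <- function(children, placements = NULL) {
  if (!is.list(children) || is(children, "PointSet")) children <- list(children)
  if (is.null(placements)) placements <- rep(list(NULL), length(children))
  if (is.matrix(placements) || is.data.frame(placements)) placements <- list(placements)
  placements <- lapply(placements, function(p) {
    if (is.null(p)) p <- matrix(0, 1L, 6L)
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  new("AssemblyNode", children = children, placements = placements)
}

#' 2D detector image
#'
#' Square matrix of intensities over (q_perp, q_z), with pixel centers at
#' (i + 1/2) * (2 qLimit / nPoints) - qLimit so that no pixel sits exactly
#' at q = 0. Pixels beyond the source's q_max are zero-filled and flagged in
#' `mask`.
#'
#' @slot values nPoints x nPoints non-negative matrix (rows: q_z ascending;
#'   columns: q_perp ascending).
#' @slot qPerp,qZ pixel-center axes (nm^-1).
#' @slot qLimit half-range per axis (nm^-1).
#' @slot phiPrime sampled azimuth (degrees) for single-orientation images,
#'   `NA` for fiber averages.
#' @slot mask logical matrix, `TRUE` where the pixel exceeded q_max.
#' @slot metadata list (seed, convergence, sample counts).
#' @exportClass DetectorImage
setClass("DetectorImage",
  representation(values = "matrix", qPerp = "numeric", qZ = "numeric",
                 qLimit = "numeric", phiPrime = "numeric", mask = "matrix",
                 metadata = "list"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("image must be square")
    if (nrow(v) %% 2L != 0L) return("nPoints must be even")
    if (any(!is.finite(v)) || any(v < 0)) return("intensities must be finite and >= 0")
    if (length(object@qPerp) != ncol(v) || length(object@qZ) != nrow(v))
      return("axis length mismatch")
    TRUE
  })

#' @rdname qValues
#' @export
imageValues <- function(x) x@values

#' @rdname qValues
#' @export
imageAxes <- function(x) list(qPerp = x@qPerp, qZ = x@qZ)

#' @rdname qValues
#' @export
imageMask <- function(x) x@mask

setMethod("show", "DetectorImage", function(object) {
  cat(sprintf("DetectorImage: %d x %d pixels, q in [%.4g, %.4g] nm^-1%s\n",
              nrow(object@values), ncol(object@values), -object@qLimit,
              object@qLimit,
              if (is.na(object@phiPrime)) " (fiber average)"
              else sprintf(", phi' = %.4g deg", object@phiPrime)))
})
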