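#' Read and write docking-list (dol) files
#'
#' A dol file is plain whitespace-separated text, one row per subunit:
#' `index x y z [alpha beta gamma]` with coordinates in nm and Tait-Bryan
#' angles in degrees; lines beginning with `#` are comments. Orientation
#' columns are optional. Round trips preserve coordinates to full double
#' precision.
#'
#' @param path file path.
#' @return `readDol` returns a [PointSet-class].
#' @export
readDol <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("dol file contains no data rows", call. = FALSE)
  box <- NULL
  hdr <- grep("^#\\s*box:", lines, value = TRUE)
  if (length(hdr)) box <- as.numeric(strsplit(sub("^#\\s*box:\\s*", "", hdr[1]), "\\s+")[[1]])
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (!(length(v) %in% c(4L, 7L)) || any(is.na(v)))
      stop(sprintf("malformed dol row at line %d: '%s'", i, lines[i]), call. = FALSE)
    v
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L)
    stop("dol rows mix 4- and 7-column formats", call. = FALSE)
  m <- do.call(rbind, rows)
  pointSet(m[, 2:4, drop = FALSE],
           orientations = if (ncols == 7L) m[, 5:7, drop = FALSE] else NULL,
           box = box)
}

#' @rdname readDol
#' @param points a [PointSet-class].
#' @param comment optional character vector of comment lines (written with
#'   a leading `#`).
#' @export
writeDol <- function(points, path, comment = character()) {
  stopifnot(is(points, "PointSet"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste("#", cm), con)
  if (!is.null(points@box))
    writeLines(sprintf("# box: %.17g %.17g %.17g", points@box[1],
                       points@box[2], points@box[3]), con)
  p <- points@positions
  o <- points@orientations
  for (i in seq_len(nrow(p))) {
    if (is.null(o))
      writeLines(sprintf("%d %.17g %.17g %.17g", i, p[i, 1], p[i, 2], p[i, 3]), con)
    else
      writeLines(sprintf("%d %.17g %.17g %.17g %.17g %.17g %.17g", i,
                         p[i, 1], p[i, 2], p[i, 3], o[i, 1], o[i, 2], o[i, 3]), con)
  }
  invisible(path)
}

#' Read and write 1D curves as two-column text
#'
#' Curves are stored as `q value` (or `r value`) pairs with `#`-prefixed
#' header lines carrying metadata as `# key: value`. The header key `type`
#' selects the class on read: `intensity` ([ScatteringCurve-class]),
#' `structure_factor` ([StructureFactorCurve-class]) or `rdf`
#' ([RDFCurve-class], whose header also records `rho_b`, `dr` and `r_max`).
#'
#' @param path file path.
#' @return `readCurve` returns a curve object of the class named in the
#'   header (defaults to [ScatteringCurve-class]).
#' @export
readCurve <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty curve file", call. = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  dataLines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(dataLines) == 0L) stop("curve file contains no data rows", call. = FALSE)
  m <- do.call(rbind, lapply(dataLines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(v) != 2L || any(is.na(v))) stop("malformed curve row", call. = FALSE)
    v
  }))
  type <- if (is.null(meta$type)) "intensity" else meta$type
  if (is.unsorted(m[, 1], strictly = TRUE))
    stop("abscissa column must be strictly ascending", call. = FALSE)
  switch(type,
    structure_factor = structureFactorCurve(m[, 1], m[, 2],
      nSubunits = if (is.null(meta$n_subunits)) 1L else as.integer(meta$n_subunits)),
    rdf = rdfCurve(m[, 1], m[, 2], rhoB = meta$rho_b, dr = meta$dr,
                   rMax = meta$r_max),
    scatteringCurve(m[, 1], m[, 2], metadata = meta[setdiff(names(meta), "type")]))
}

#' @rdname readCurve
#' @param curve a [ScatteringCurve-class], [StructureFactorCurve-class] or
#'   [RDFCurve-class].
#' @export
writeCurve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeMeta <- function(key, val) {
    if (is.numeric(val) && length(val) == 1L)
      writeLines(sprintf("# %s: %.17g", key, val), con)
    else if (is.character(val) && length(val) == 1L)
      writeLines(sprintf("# %s: %s", key, val), con)
    else if (is.logical(val) && length(val) == 1L)
      writeLines(sprintf("# %s: %s", key, val), con)
  }
  if (is(curve, "StructureFactorCurve")) {
    writeMeta("type", "structure_factor")
    writeMeta("n_subunits", curve@nSubunits)
    xy <- cbind(curve@q, curve@S)
  } else if (is(curve, "RDFCurve")) {
    writeMeta("type", "rdf")
    writeMeta("rho_b", curve@rhoB)
    writeMeta("dr", curve@dr)
    writeMeta("r_max", curve@rMax)
    xy <- cbind(curve@r, curve@g)
  } else if (is(curve, "ScatteringCurve")) {
    writeMeta("type", "intensity")
    for (nm in names(curve@metadata)) writeMeta(nm, curve@metadata[[nm]])
    xy <- cbind(curve@q, curve@I)
  } else stop("unsupported curve class", call. = FALSE)
  writeLines(sprintf("%.17g %.17g", xy[, 1], xy[, 2]), con)
  invisible(path)
}

#' Persist reciprocal grids as a plain-text container
#'
#' The container holds `# key: value` attribute lines (q_max, n_shells,
#' format version) followed by one `Re Im` pair per node in storage order;
#' the layout itself is reconstructed deterministically from n_shells.
#' Round trips are exact to double precision.
#'
#' @param grid a [ReciprocalGrid-class].
#' @param path file path.
#' @export
writeGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# format: oriscat-grid 1",
               sprintf("# q_max: %.17g", grid@qMax),
               sprintf("# n_shells: %d", grid@nShells)), con)
  writeLines(sprintf("%.17g %.17g", Re(grid@values), Im(grid@values)), con)
  invisible(path)
}

#' @rdname writeGrid
#' @export
readGrid <- function(path) {
  lines <- readLines(path)
  getAttr <- function(key) {
    h <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (!length(h)) stop(sprintf("grid container lacks attribute '%s'", key), call. = FALSE)
    sub(sprintf("^#\\s*%s:\\s*", key), "", h[1])
  }
  qMax <- as.numeric(getAttr("q_max"))
  nShells <- as.integer(getAttr("n_shells"))
  dataLines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(dataLines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  lay <- gridLayout(qMax, nShells)
  if (nrow(m) != lay$nNodes) stop("grid value count does not match layout", call. = FALSE)
  new("ReciprocalGrid", qMax = qMax, nShells = nShells, shellQ = lay$shellQ,
      shellTheta = lay$shellTheta, rowNphi = lay$rowNphi,
      rowOffset = lay$rowOffset, values = complex(real = m[, 1], imaginary = m[, 2]))
}
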