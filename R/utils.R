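# Internal numerical helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# sinc(x) = sin(x)/x with the removable singularity at 0.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# Tait-Bryan rotation matrix: intrinsic rotations alpha about x, then beta
# about y, then gamma about z (angles in degrees). Acts on column vectors.
taitBryanMatrix <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Composite Simpson on a uniform grid; falls back to trapezoid on the final
# interval when the point count is even.
simpsonUniform <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(0)
  if (n == 2L) return(h * (y[1] + y[2]) / 2)
  if (n %% 2L == 1L) {
    w <- rep(c(4, 2), length.out = n - 2L)
    return(h / 3 * (y[1] + y[n] + sum(w * y[2:(n - 1L)])))
  }
  simpsonUniform(y[1:(n - 1L)], h) + h * (y[n - 1L] + y[n]) / 2
}

# Discrete sine transform, type I: X_k = sum_{n=1}^{N} x_n sin(pi n k / (N+1)),
# computed through a length-2(N+1) FFT of the odd extension.
dstI <- function(x) {
  n <- length(x)
  y <- c(0, x, 0, -rev(x))
  ft <- stats::fft(y)
  -Im(ft[2:(n + 1L)]) / 2
}

# Pairwise distances with optional minimum-image convention; returns the
# vector of the n(n-1)/2 unique distances.
pairDistances <- function(pos, box = NULL) {
  if (is.null(box)) return(as.numeric(stats::dist(pos)))
  n <- nrow(pos)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    d <- sweep(pos[(i + 1L):n, , drop = FALSE], 2L, pos[i, ])
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    out[[i]] <- sqrt(rowSums(d^2))
  }
  unlist(out)
}

# Distances from one reference point to all others (minimum image if box).
distancesFrom <- function(pos, i, box = NULL) {
  d <- sweep(pos[-i, , drop = FALSE], 2L, pos[i, ])
  if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d^2))
}

# Uniform random directions on the unit sphere (area-preserving map).
randomDirections <- function(n) {
  phi <- 2 * pi * stats::runif(n)
  ct <- 2 * stats::runif(n) - 1
  st <- sqrt(pmax(0, 1 - ct^2))
  cbind(st * cos(phi), st * sin(phi), ct)
}

stopIfNotFinite <- function(x, what) {
  if (any(!is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
  invisible(x)
}

# Coerce q-vector input to an n x 3 matrix.
asQMatrix <- function(qvec) {
  if (is.vector(qvec) && length(qvec) == 3L) qvec <- matrix(qvec, 1L, 3L)
  qvec <- as.matrix(qvec)
  if (ncol(qvec) != 3L) stop("q vectors must have 3 components", call. = FALSE)
  stopIfNotFinite(qvec, "q vectors")
  qvec
}
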