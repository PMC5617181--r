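#' @useDynLib fiberslice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats smooth.spline splinefun predict sd median integrate
#'   uniroot rnorm runif quantile approx dist spline
#' @importFrom utils write.csv head tail
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Run code with a local RNG state so package internals never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_matrix3 <- function(points) {
  p <- as.matrix(points)
  if (is.null(dim(p)) || ncol(p) != 3)
    stop("expected an n x 3 matrix of 3D points")
  storage.mode(p) <- "double"
  unname(p)
}

# --- array interpolation (indices are 0-based voxel coordinates) -------------

#' Trilinear interpolation into a 3D array
#'
#' Samples a `(z, y, x)`-indexed array at fractional 0-based voxel
#' coordinates. Out-of-range samples receive `fill` and are flagged invalid.
#'
#' @param a 3D numeric array indexed `(z, y, x)`.
#' @param zyx n x 3 matrix of fractional 0-based `(z, y, x)` coordinates.
#' @param fill value assigned to samples outside the grid.
#' @param clamp if `TRUE`, out-of-range samples take the clamped border value
#'   instead of `fill` (they are still flagged invalid).
#' @return list with `values` (length n) and `valid` (logical length n).
#' @keywords internal
interp_trilinear <- function(a, zyx, fill = 0, clamp = FALSE) {
  d <- dim(a)
  if (any(d < 2)) stop("interpolation requires >= 2 samples per axis")
  z <- zyx[, 1]; y <- zyx[, 2]; x <- zyx[, 3]
  valid <- z >= 0 & z <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    x >= 0 & x <= d[3] - 1 & is.finite(z) & is.finite(y) & is.finite(x)
  z <- pmin(pmax(z, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  x <- pmin(pmax(x, 0), d[3] - 1)
  z0 <- pmin(floor(z), d[1] - 2); fz <- z - z0
  y0 <- pmin(floor(y), d[2] - 2); fy <- y - y0
  x0 <- pmin(floor(x), d[3] - 2); fx <- x - x0
  lin <- function(zi, yi, xi) a[xi * d[1] * d[2] + yi * d[1] + zi + 1]
  v <- lin(z0, y0, x0) * (1 - fz) * (1 - fy) * (1 - fx) +
    lin(z0 + 1, y0, x0) * fz * (1 - fy) * (1 - fx) +
    lin(z0, y0 + 1, x0) * (1 - fz) * fy * (1 - fx) +
    lin(z0, y0, x0 + 1) * (1 - fz) * (1 - fy) * fx +
    lin(z0 + 1, y0 + 1, x0) * fz * fy * (1 - fx) +
    lin(z0 + 1, y0, x0 + 1) * fz * (1 - fy) * fx +
    lin(z0, y0 + 1, x0 + 1) * (1 - fz) * fy * fx +
    lin(z0 + 1, y0 + 1, x0 + 1) * fz * fy * fx
  if (!clamp) v[!valid] <- fill
  list(values = v, valid = valid)
}

# Catmull-Rom (Keys, a = -1/2) cubic convolution weights for offsets -1..2
cubic_weights <- function(t) {
  a <- -0.5
  w <- matrix(0, length(t), 4)
  s <- 1 + t
  w[, 1] <- a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a
  w[, 2] <- (a + 2) * t^3 - (a + 3) * t^2 + 1
  s <- 1 - t
  w[, 3] <- (a + 2) * s^3 - (a + 3) * s^2 + 1
  s <- 2 - t
  w[, 4] <- a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a
  w
}

#' @rdname interp_trilinear
#' @keywords internal
interp_tricubic <- function(a, zyx, fill = 0) {
  d <- dim(a)
  z <- zyx[, 1]; y <- zyx[, 2]; x <- zyx[, 3]
  valid <- z >= 0 & z <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    x >= 0 & x <= d[3] - 1 & is.finite(z) & is.finite(y) & is.finite(x)
  z <- pmin(pmax(z, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  x <- pmin(pmax(x, 0), d[3] - 1)
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  wz <- cubic_weights(z - z0); wy <- cubic_weights(y - y0)
  wx <- cubic_weights(x - x0)
  clampi <- function(i, n) pmin(pmax(i, 0), n - 1)
  v <- numeric(nrow(zyx))
  for (kz in 1:4) {
    zi <- clampi(z0 + kz - 2, d[1])
    for (ky in 1:4) {
      yi <- clampi(y0 + ky - 2, d[2])
      wzy <- wz[, kz] * wy[, ky]
      for (kx in 1:4) {
        xi <- clampi(x0 + kx - 2, d[3])
        v <- v + wzy * wx[, kx] * a[xi * d[1] * d[2] + yi * d[1] + zi + 1]
      }
    }
  }
  v[!valid] <- fill
  list(values = v, valid = valid)
}

# --- separable Gaussian smoothing -------------------------------------------

shift_along_axis <- function(a, axis, off) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis]) # clamp edges
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param a 3D numeric array.
#' @param sigma_vox per-axis standard deviation in voxels (length 3, order
#'   matching `dim(a)`); zero skips the axis. Edges are clamp-padded.
#' @return smoothed array of the same dimensions.
#' @keywords internal
gaussian_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2) { # promote 2D
    dim(a) <- c(d, 1L)
    out <- gaussian_blur3(a, c(sigma_vox[1:2], 0))
    dim(out) <- d
    return(out)
  }
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_along_axis(a, axis, j - r - 1L)
    }
    a <- acc
  }
  a
}

# Gaussian smoothing of each column of a matrix (used to steady skeleton
# points before tangent estimation); sigma in units of points.
gaussian_smooth_cols <- function(m, sigma_pts) {
  if (sigma_pts <= 0 || nrow(m) < 3) return(m)
  r <- max(1L, ceiling(3 * sigma_pts))
  k <- exp(-((-r):r)^2 / (2 * sigma_pts^2))
  k <- k / sum(k)
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  out
}
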