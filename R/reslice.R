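#' Template grid of in-plane sample offsets
#'
#' A `(2R+1) x (2C+1)` lattice of 2D offsets centered on `(0, 0)`, in
#' micrometers. Rows run along the plane's first axis (normal direction `u`),
#' columns along the second (`v`), which carries the sweeping line `a1` from
#' offset `(0, -C)` to `(0, C)`.
#'
#' @param R,C half-extents of the grid (>= 1, grid units).
#' @param sample_spacing in-plane sample spacing, micrometers.
#' @return list with `du` (row offsets, length `2R+1`), `dv` (column offsets,
#'   length `2C+1`), `spacing`, `R`, `C`.
#' @export
build_plane_grid <- function(R, C, sample_spacing) {
  if (R < 1 || C < 1) stop("plane half-extents must be >= 1")
  if (sample_spacing <= 0) stop("sample spacing must be positive")
  list(du = (-R:R) * sample_spacing, dv = (-C:C) * sample_spacing,
       spacing = sample_spacing, R = as.integer(R), C = as.integer(C))
}

#' Resample a volume into resliced image space
#'
#' Places one cross-sectional plane per curve point, oriented by the
#' consistent frames (plane normal = curve tangent, in-plane axes = normal
#' and binormal), and samples the volume on the plane grid. Samples falling
#' outside the volume receive `fill` and are flagged invalid. Each plane's
#' rigid transform (rotation + translation) is retained so segmented points
#' can be mapped back to original space.
#'
#' @param volume a [image_volume()].
#' @param curve a [curve3d()] in physical micrometers.
#' @param frames a [propagate_consistent_frames()] result matching `curve`.
#' @param grid a [build_plane_grid()] template.
#' @param interpolation `"trilinear"` or `"spline"` (cubic convolution).
#' @param fill value for out-of-volume samples.
#' @return object of class `reslice_stack`: intensities
#'   `[slice, 2R+1, 2C+1]`, a congruent `valid` array, plane `centers`, the
#'   `frames`, the `grid`, and the source volume spacing.
#' @export
reslice_volume <- function(volume, curve, frames, grid,
                           interpolation = c("trilinear", "spline"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(volume, "fiber_volume"))
  p <- unclass(curve)
  n <- nrow(p)
  if (nrow(frames$tangent) != n)
    stop("frames do not match the curve length")
  nr <- 2L * grid$R + 1L
  nc <- 2L * grid$C + 1L
  off <- cbind(a = rep(grid$du, times = nc), b = rep(grid$dv, each = nr))
  # all sample positions, slice-major
  pts <- matrix(0, n * nr * nc, 3)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * nr * nc + 1):(i * nr * nc)
    pts[rows, ] <- matrix(p[i, ], nr * nc, 3, byrow = TRUE) +
      off[, 1] %o% frames$normal[i, ] + off[, 2] %o% frames$binormal[i, ]
  }
  zyx <- physical_to_voxel(pts, volume)
  res <- if (interpolation == "trilinear") {
    interp_trilinear(volume$data, zyx, fill = fill)
  } else {
    interp_tricubic(volume$data, zyx, fill = fill)
  }
  intens <- array(res$values, c(nr, nc, n))
  valid <- array(res$valid, c(nr, nc, n))
  intens <- aperm(intens, c(3, 1, 2))
  valid <- aperm(valid, c(3, 1, 2))
  structure(list(intensities = intens, valid = valid, centers = p,
                 frames = frames, grid = grid,
                 voxel_spacing = volume$spacing,
                 interpolation = interpolation, fill = fill),
            class = "reslice_stack")
}

#' @export
print.reslice_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<reslice_stack> %d planes of %d x %d samples (%.3g um/sample)\n",
              d[1], d[2], d[3], x$grid$spacing))
  invisible(x)
}

plane_rotation <- function(stack, i) {
  cbind(stack$frames$normal[i, ], stack$frames$binormal[i, ],
        stack$frames$tangent[i, ])
}

interp_plane_transform <- function(stack, s) {
  n <- nrow(stack$centers)
  if (s < 1 || s > n) stop("slice index out of range: ", s)
  i0 <- floor(s)
  if (i0 == s || i0 >= n) {
    return(list(R = plane_rotation(stack, as.integer(s)),
                center = stack$centers[as.integer(s), ]))
  }
  f <- s - i0
  lerp <- function(m) (1 - f) * m[i0, ] + f * m[i0 + 1, ]
  t <- normalize(lerp(stack$frames$tangent))
  u <- lerp(stack$frames$normal)
  u <- normalize(u - sum(u * t) * t)
  list(R = cbind(u, cross3(t, u), t), center = lerp(stack$centers))
}

#' Express an original-space point in a plane's coordinates
#'
#' @param stack a [reslice_volume()] result.
#' @param i slice index (integer).
#' @param point physical `(x, y, z)` point, micrometers.
#' @return length-3 vector `(a, b, c)`: offsets along the plane's normal
#'   axis, sweeping-line axis and out-of-plane (tangent) axis.
#' @export
to_plane_coords <- function(stack, i, point) {
  tr <- interp_plane_transform(stack, i)
  as.numeric(crossprod(tr$R, as.numeric(point) - tr$center))
}

#' Map resliced-space points back to original physical space
#'
#' Applies the inverse of each plane's rigid transform. Fractional slice
#' indices interpolate between neighboring plane transforms (positions
#' linearly, axes re-orthonormalized).
#'
#' @param points matrix with columns `(slice, a, b)` or `(slice, a, b, c)`:
#'   1-based slice index (fractions allowed) and in-plane offsets in
#'   micrometers (`c` = out-of-plane offset, default 0).
#' @param stack a [reslice_volume()] result.
#' @return n x 3 matrix of physical `(x, y, z)` points (in general a point
#'   cloud, not a voxel grid).
#' @export
map_back <- function(points, stack) {
  pts <- as.matrix(points)
  if (ncol(pts) == 3) pts <- cbind(pts, 0)
  n <- nrow(stack$centers)
  if (any(pts[, 1] < 1 | pts[, 1] > n))
    stop("slice index out of range in map_back()")
  out <- matrix(0, nrow(pts), 3)
  colnames(out) <- c("x", "y", "z")
  frac <- pts[, 1] != round(pts[, 1])
  # integer slices resolved in bulk, per unique slice
  for (i in unique(pts[!frac, 1])) {
    sel <- !frac & pts[, 1] == i
    R <- plane_rotation(stack, as.integer(i))
    out[sel, ] <- pts[sel, 2:4, drop = FALSE] %*% t(R) +
      matrix(stack$centers[as.integer(i), ], sum(sel), 3, byrow = TRUE)
  }
  for (k in which(frac)) {
    tr <- interp_plane_transform(stack, pts[k, 1])
    out[k, ] <- as.numeric(tr$R %*% pts[k, 2:4]) + tr$center
  }
  out
}

#' Resliced-space mask samples as (slice, a, b) offset triples
#'
#' Convenience for feeding a segmented resliced mask to [map_back()].
#'
#' @param stack a [reslice_volume()] result.
#' @param mask logical array congruent with `stack$intensities`.
#' @return matrix with columns `(slice, a, b)`.
#' @export
mask_to_plane_points <- function(stack, mask) {
  if (!all(dim(mask) == dim(stack$intensities)))
    stop("mask shape does not match the reslice stack")
  idx <- which(mask, arr.ind = TRUE)
  cbind(slice = idx[, 1],
        a = stack$grid$du[idx[, 2]],
        b = stack$grid$dv[idx[, 3]])
}

#' Flatten a reslice stack into a longitudinal image
#'
#' One row per slice: the intensity profile along each plane's sweeping line
#' `a1` (the central grid row), in curve order. This is the flattened view of
#' a traditional curved planar reformation.
#'
#' @param stack a [reslice_volume()] result.
#' @return matrix of size `n_slices x (2C+1)`.
#' @export
flatten_cpr <- function(stack) {
  d <- dim(stack$intensities)
  out <- stack$intensities[, stack$grid$R + 1L, , drop = FALSE]
  dim(out) <- c(d[1], d[3])
  out
}
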