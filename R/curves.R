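#' Ordered 3D curve with arc length
#'
#' Sub-voxel polyline through physical space: an ordered sequence of distinct
#' `(x, y, z)` points in micrometers carrying cumulative arc length.
#'
#' @param points n x 3 matrix of `(x, y, z)` positions, micrometers, n >= 2.
#' @return object of class `fiber_curve`: the point matrix with an
#'   `arc_length` attribute (cumulative, starting at 0).
#' @export
curve3d <- function(points) {
  p <- as_matrix3(points)
  if (nrow(p) < 2) stop("a curve needs at least 2 points")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) {
    stop("consecutive curve points coincide at index ",
         which(seg == 0)[1])
  }
  colnames(p) <- c("x", "y", "z")
  structure(p, arc_length = c(0, cumsum(seg)), class = "fiber_curve")
}

#' @export
print.fiber_curve <- function(x, ...) {
  cat(sprintf("<fiber_curve> %d points, length %.3f um\n",
              nrow(x), total_length(x)))
  invisible(x)
}

#' @rdname curve3d
#' @param curve a `fiber_curve`.
#' @return `total_length()`: total arc length in micrometers;
#'   `arc_lengths()`: the cumulative arc length at each point.
#' @export
total_length <- function(curve) {
  s <- attr(curve, "arc_length")
  s[length(s)]
}

#' @rdname curve3d
#' @export
arc_lengths <- function(curve) attr(curve, "arc_length")

#' Unit tangents along a curve by center differences
#'
#' Interior points use the central difference `p[i+1] - p[i-1]`; the two
#' endpoints use one-sided differences. All tangents are normalized.
#'
#' @param curve a [curve3d()] (n >= 2 points).
#' @return n x 3 matrix of unit tangent vectors.
#' @export
compute_tangents <- function(curve) {
  p <- unclass(curve)
  n <- nrow(p)
  d <- matrix(0, n, 3)
  d[1, ] <- p[2, ] - p[1, ]
  d[n, ] <- p[n, ] - p[n - 1, ]
  if (n > 2) d[2:(n - 1), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  bad <- which(len < 1e-12)
  if (length(bad)) {
    stop("degenerate geometry: zero tangent at curve point ", bad[1])
  }
  d / len
}
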