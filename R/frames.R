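#' Rotation matrix about an axis (Rodrigues' formula)
#'
#' @param axis 3-vector, normalized internally; must be nonzero.
#' @param angle_deg rotation angle in degrees, right-hand sense about `axis`.
#' @return 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- normalize(as.numeric(axis))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Initial cross-sectional plane axes for a tangent
#'
#' The reference plane is horizontal with normal `[0, 0, 1]` and in-plane
#' axes `u = (0, 1, 0)`, `v = (1, 0, 0)` (the sweeping-line axis). It is
#' carried onto the tangent by the tangent's azimuth and altitude: an
#' elevation rotation about the y axis followed by an azimuth rotation about
#' z. Continuous in the tangent except at the `+/- z` poles, where the
#' azimuth defaults to 0.
#'
#' @param tangent unit 3-vector (plane normal).
#' @return list with unit in-plane axes `u` and `v`, both orthogonal to the
#'   tangent and to each other.
#' @export
align_plane_to_tangent <- function(tangent) {
  t <- normalize(as.numeric(tangent))
  azim <- if (abs(t[1]) < 1e-12 && abs(t[2]) < 1e-12) 0 else atan2(t[2], t[1])
  alt <- asin(max(-1, min(1, t[3])))
  R <- rotation_about_axis(c(0, 0, 1), rad2deg(azim)) %*%
    rotation_about_axis(c(0, 1, 0), rad2deg(pi / 2 - alt))
  list(u = as.numeric(R %*% c(0, 1, 0)),
       v = as.numeric(R %*% c(1, 0, 0)))
}

#' Consistent (rotation-minimizing) frames along a curve
#'
#' Builds one orthonormal triad \{tangent, normal, binormal\} per curve point
#' with the plane normal identified with the curve tangent. The first frame
#' comes from [align_plane_to_tangent()]; each subsequent \{normal, binormal\}
#' pair is the previous pair rotated about the local tangent by the angle that
#' maximizes the dot product between consecutive normals. The closed form of
#' that maximizer is the projection of the previous normal onto the plane
#' orthogonal to the current tangent, renormalized; the binormal follows as
#' `tangent x normal`. This eliminates the Frenet frame's flips at curvature
#' sign changes (inflections) and its indeterminacy on straight runs.
#'
#' @param curve a [curve3d()].
#' @param tangents optional precomputed unit tangents ([compute_tangents()]).
#' @return object of class `fiber_frames`: list with n x 3 matrices
#'   `tangent`, `normal`, `binormal` and per-step achieved rotation angles
#'   `step_angle_deg` (length n, first entry 0).
#' @export
propagate_consistent_frames <- function(curve, tangents = NULL) {
  if (is.null(tangents)) tangents <- compute_tangents(curve)
  n <- nrow(tangents)
  nor <- matrix(0, n, 3)
  bin <- matrix(0, n, 3)
  ang <- numeric(n)
  f0 <- align_plane_to_tangent(tangents[1, ])
  nor[1, ] <- f0$u
  bin[1, ] <- cross3(tangents[1, ], nor[1, ])
  for (i in 2:n) {
    t_i <- tangents[i, ]
    proj <- nor[i - 1, ] - sum(nor[i - 1, ] * t_i) * t_i
    if (vnorm(proj) < 1e-9) {
      warning("normal parallel to tangent at point ", i,
              "; re-seeding frame from the tangent's azimuth/altitude")
      f <- align_plane_to_tangent(t_i)
      nor[i, ] <- f$u
    } else {
      nor[i, ] <- proj / vnorm(proj)
    }
    bin[i, ] <- cross3(t_i, nor[i, ])
    d <- max(-1, min(1, sum(nor[i - 1, ] * nor[i, ])))
    ang[i] <- rad2deg(acos(d))
  }
  structure(list(tangent = tangents, normal = nor, binormal = bin,
                 step_angle_deg = ang),
            class = "fiber_frames")
}

#' @export
print.fiber_frames <- function(x, ...) {
  cat(sprintf("<fiber_frames> %d triads, max step rotation %.3f deg\n",
              nrow(x$tangent), max(x$step_angle_deg)))
  invisible(x)
}
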