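#' Waviness (tortuosity ratio) of a curve
#'
#' Arc length of the polyline divided by the Euclidean distance between its
#' endpoints; 1 for a straight fiber. Invariant under rigid motion and
#' uniform scaling.
#'
#' @param curve a [curve3d()] (or n x 3 matrix) with distinct endpoints.
#' @return waviness, dimensionless, >= 1.
#' @export
waviness <- function(curve) {
  p <- as_matrix3(unclass(curve))
  if (nrow(p) < 2) stop("waviness needs at least 2 points")
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord < 1e-9)
    stop("coincident curve endpoints: waviness of a closed loop is undefined")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  sum(seg) / chord
}

#' Tilt (latitude) angle of a curve
#'
#' The fiber's out-of-plane excursion: the ratio of the maximal z-coordinate
#' difference along the curve to the XY-plane distance between its endpoint
#' projections, converted to degrees as `atan(ratio)`. Invariant under
#' rotation about the z axis and translation. A fiber with no XY extent is
#' reported as 90 degrees with a warning.
#'
#' @param curve a [curve3d()] (or n x 3 matrix).
#' @return tilt angle in degrees, in `[0, 90]`.
#' @export
tilt <- function(curve) {
  p <- as_matrix3(unclass(curve))
  if (nrow(p) < 2) stop("tilt needs at least 2 points")
  dz <- max(p[, 3]) - min(p[, 3])
  dxy <- sqrt(sum((p[nrow(p), 1:2] - p[1, 1:2])^2))
  if (dxy < 1e-9) {
    warning("vertical fiber: XY endpoint distance is zero; reporting 90 degrees")
    return(90)
  }
  rad2deg(atan(dz / dxy))
}

#' Planar cross section of a mesh
#'
#' Intersects the plane through `point` with normal `normal` with every mesh
#' triangle, assembles the resulting segments into closed loops by shared
#' mesh-edge endpoints, selects the loop whose centroid lies nearest the
#' query point, and returns its area by the shoelace formula in plane
#' coordinates.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param point physical `(x, y, z)` point on the skeleton, micrometers.
#' @param normal unit plane normal (the local skeleton tangent).
#' @param search_radius maximum allowed centroid distance from `point`
#'   (micrometers); `NULL` disables the check.
#' @return list with `area` (um^2), `polygon` (k x 2 loop in plane
#'   coordinates), `loop3d` (k x 3), `centroid_dist` (um); or `NULL` when the
#'   plane cuts no closed loop within reach.
#' @export
cross_section <- function(mesh, point, normal, search_radius = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- normalize(as.numeric(normal))
  point <- as.numeric(point)
  sd <- as.numeric((v - matrix(point, nrow(v), 3, TRUE)) %*% n)
  side <- sd > 0
  s1 <- side[f[, 1]]; s2 <- side[f[, 2]]; s3 <- side[f[, 3]]
  cut <- which((s1 != s2) | (s2 != s3))
  if (!length(cut)) return(NULL)
  # for each cut triangle find its two crossed edges; key edges globally so
  # shared edges between triangles yield identical intersection points
  edge_key <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    paste(lo, hi)
  }
  seg_from <- character(0); seg_to <- character(0)
  keys <- character(0)
  key_pt <- list()
  tri_edges <- function(tri) {
    e <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    crossed <- side[e[, 1]] != side[e[, 2]]
    e[crossed, , drop = FALSE]
  }
  for (ti in cut) {
    e <- tri_edges(f[ti, ])
    if (nrow(e) != 2) next # vertex exactly on plane: rare, skip triangle
    ks <- character(2)
    for (j in 1:2) {
      k <- edge_key(e[j, 1], e[j, 2])
      if (is.null(key_pt[[k]])) {
        d1 <- sd[e[j, 1]]; d2 <- sd[e[j, 2]]
        t <- d1 / (d1 - d2)
        key_pt[[k]] <- v[e[j, 1], ] + t * (v[e[j, 2], ] - v[e[j, 1], ])
      }
      ks[j] <- k
    }
    seg_from <- c(seg_from, ks[1]); seg_to <- c(seg_to, ks[2])
  }
  if (!length(seg_from)) return(NULL)
  # loops: every key appears in exactly two segments (watertight mesh)
  nodes <- unique(c(seg_from, seg_to))
  gi <- igraph::graph_from_edgelist(cbind(match(seg_from, nodes),
                                          match(seg_to, nodes)),
                                    directed = FALSE)
  comps <- igraph::components(gi)
  basis <- align_plane_to_tangent(n)
  best <- NULL
  for (cid in seq_len(comps$no)) {
    vids <- which(comps$membership == cid)
    if (length(vids) < 3) next
    sub <- igraph::induced_subgraph(gi, vids)
    if (any(igraph::degree(sub) != 2)) next # open chain, not a loop
    # walk the cycle
    ord <- integer(length(vids))
    ord[1] <- 1L
    prev <- -1L
    for (i in seq_along(vids)[-1]) {
      nbrs <- as.integer(igraph::neighbors(sub, ord[i - 1]))
      nxt <- nbrs[nbrs != prev][1]
      prev <- ord[i - 1]
      ord[i] <- nxt
    }
    pts3 <- do.call(rbind, key_pt[nodes[vids[ord]]])
    rel <- pts3 - matrix(point, nrow(pts3), 3, TRUE)
    poly <- cbind(rel %*% basis$u, rel %*% basis$v)
    k <- nrow(poly)
    area <- abs(sum(poly[, 1] * poly[c(2:k, 1), 2] -
                      poly[c(2:k, 1), 1] * poly[, 2])) / 2
    ctr <- colMeans(pts3)
    cdist <- sqrt(sum((ctr - point)^2))
    if (is.null(best) || cdist < best$centroid_dist) {
      best <- list(area = area, polygon = poly, loop3d = pts3,
                   centroid_dist = cdist)
    }
  }
  if (is.null(best)) return(NULL)
  if (!is.null(search_radius) && best$centroid_dist > search_radius)
    return(NULL)
  best
}

#' Cross-sectional area and diameter series along a skeleton
#'
#' Cuts the fiber mesh perpendicular to the (optionally smoothed) skeleton at
#' every skeleton point, using center-difference tangents as plane normals.
#' The equivalent diameter is that of the circle with the measured area,
#' `2 sqrt(A / pi)`. Points with no closed loop nearby, or with diameter
#' above the outlier threshold, are flagged and excluded from the summary.
#'
#' @param mesh a [surface_mesh()] of the fiber surface.
#' @param skeleton a [curve3d()], ideally spline-resampled
#'   ([resample_spline()]).
#' @param outlier_diameter diameter flag threshold, micrometers (default 6).
#' @param smooth_sigma_pts Gaussian smoothing of the skeleton (in points)
#'   before tangent estimation; reduces outliers from inaccurate normals.
#' @param search_factor a loop is rejected when its centroid is farther from
#'   the skeleton point than `search_factor` times the running median
#'   diameter.
#' @return data.frame with one row per skeleton point: `point_index`,
#'   `arc_length_um`, `csa_um2`, `diameter_um`, `outlier`; summary attributes
#'   `mean_csa`, `sd_csa`, `mean_diameter`, `sd_diameter`,
#'   `outlier_fraction`.
#' @export
measure_csa_series <- function(mesh, skeleton, outlier_diameter = 6,
                               smooth_sigma_pts = 2, search_factor = 2) {
  p <- unclass(skeleton)
  if (smooth_sigma_pts > 0) {
    ps <- gaussian_smooth_cols(p, smooth_sigma_pts)
    sk <- curve3d(ps)
  } else {
    sk <- skeleton
  }
  tg <- compute_tangents(sk)
  n <- nrow(p)
  s <- attr(skeleton, "arc_length")
  csa <- rep(NA_real_, n)
  cdist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cs <- cross_section(mesh, unclass(sk)[i, ], tg[i, ])
    if (!is.null(cs)) {
      csa[i] <- cs$area
      cdist[i] <- cs$centroid_dist
    }
  }
  diam <- 2 * sqrt(csa / pi)
  med <- median(diam[!is.na(diam) & diam <= outlier_diameter], na.rm = TRUE)
  stray <- !is.na(cdist) & is.finite(med) & cdist > search_factor * med
  outlier <- is.na(csa) | diam > outlier_diameter | stray
  if (all(outlier)) stop("every skeleton point was flagged; no usable cross sections")
  out <- data.frame(point_index = seq_len(n), arc_length_um = s,
                    csa_um2 = csa, diameter_um = diam, outlier = outlier)
  ok <- !outlier
  attr(out, "mean_csa") <- mean(csa[ok])
  attr(out, "sd_csa") <- sd(csa[ok])
  attr(out, "mean_diameter") <- mean(diam[ok])
  attr(out, "sd_diameter") <- sd(diam[ok])
  attr(out, "outlier_fraction") <- mean(outlier)
  out
}

#' In-plane orientation from second central moments
#'
#' Principal-axis angle of a 2D region (or point set):
#' `theta = 0.5 * atan2(2 mu11, mu20 - mu02)`, measured from the +x axis and
#' mapped into `[0, 180)`.
#'
#' @param region logical matrix (a 2D mask; rows = y, columns = x) or an
#'   n x 2 matrix of `(x, y)` points.
#' @param spacing pixel spacing `(y, x)` for mask input.
#' @return orientation in degrees, `[0, 180)`.
#' @export
orientation_2d <- function(region, spacing = c(1, 1)) {
  if (is.logical(region) && length(dim(region)) == 2) {
    idx <- which(region, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty region")
    pts <- cbind(x = (idx[, 2] - 1) * spacing[2],
                 y = (idx[, 1] - 1) * spacing[1])
  } else {
    pts <- as.matrix(region)
    if (ncol(pts) != 2) stop("expected a 2D mask or n x 2 points")
  }
  if (nrow(pts) < 2) stop("orientation of a single point is undefined")
  mu <- colMeans(pts)
  dx <- pts[, 1] - mu[1]
  dy <- pts[, 2] - mu[2]
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  if (abs(mu20 - mu02) < 1e-12 && abs(mu11) < 1e-12)
    stop("isotropic region: orientation undefined")
  th <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  ang <- rad2deg(th) %% 180
  ang
}

# circular mean and SD of axial angles (period 180 deg) via angle doubling
axial_stats <- function(angles_deg) {
  phi <- deg2rad(2 * angles_deg)
  C <- mean(cos(phi)); S <- mean(sin(phi))
  R <- sqrt(C^2 + S^2)
  mean_deg <- (rad2deg(atan2(S, C)) / 2) %% 180
  sd_deg <- if (R >= 1) 0 else rad2deg(sqrt(-2 * log(R))) / 2
  list(mean = mean_deg, sd = sd_deg, R = R)
}

#' Split axial angles into two orientation populations
#'
#' Two-cluster split on the 180-degree circle: angles are doubled onto the
#' full circle, where the optimal two clusters are contiguous arcs of the
#' sorted sequence; all arc splits are scored by the summed resultant
#' lengths (equivalently, minimal circular variance) and the best is kept.
#' Angles wrapping past 0/180 are assigned by circular distance, so values
#' just below 180 join a near-0 peak.
#'
#' @param angles_deg numeric vector of axial angles (degrees), length >= 4.
#' @return list with per-group `mean` and `sd` (degrees, axial scale
#'   `[0, 180)`), `assignment` (1/2 per input angle, group 1 has the smaller
#'   mean), and `n` per group. Identical inputs give a single group with a
#'   warning.
#' @export
split_bimodal <- function(angles_deg) {
  a <- as.numeric(angles_deg) %% 180
  if (length(a) < 4) stop("need at least 4 angles")
  if (diff(range(a)) < 1e-9) {
    warning("all angles identical; returning a single group")
    st <- axial_stats(a)
    return(list(groups = list(c(mean = st$mean, sd = st$sd)),
                assignment = rep(1L, length(a)), n = length(a)))
  }
  phi <- (2 * a) %% 360
  ord <- order(phi)
  ps <- phi[ord]
  n <- length(ps)
  cs <- cumsum(cos(deg2rad(ps)))
  ss <- cumsum(sin(deg2rad(ps)))
  # resultant length of the arc (i+1..j) in sorted circular order
  arcR <- function(i, j) { # i < j indices into ps
    C <- cs[j] - cs[i]; S <- ss[j] - ss[i]
    sqrt(C^2 + S^2)
  }
  best <- NULL
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    # cluster A = elements i+1..j, cluster B = the rest (wrapping arc)
    nA <- j - i
    if (nA == n) next
    CA <- cs[j] - if (i > 0) cs[i] else 0
    SA <- ss[j] - if (i > 0) ss[i] else 0
    CB <- cs[n] - CA; SB <- ss[n] - SA
    score <- sqrt(CA^2 + SA^2) + sqrt(CB^2 + SB^2)
    if (is.null(best) || score > best$score) best <- list(i = i, j = j, score = score)
  }
  inA <- rep(FALSE, n)
  inA[(best$i + 1):best$j] <- TRUE
  grpA <- a[ord][inA]
  grpB <- a[ord][!inA]
  stA <- axial_stats(grpA); stB <- axial_stats(grpB)
  if (stB$mean < stA$mean) {
    tmp <- stA; stA <- stB; stB <- tmp
    inA <- !inA
    tmpg <- grpA; grpA <- grpB; grpB <- tmpg
  }
  assignment <- integer(length(a))
  assignment[ord] <- ifelse(inA, 1L, 2L)
  list(groups = list(c(mean = stA$mean, sd = stA$sd),
                     c(mean = stB$mean, sd = stB$sd)),
       assignment = assignment,
       n = c(length(grpA), length(grpB)))
}
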