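#' Euclidean distance-to-background transform
#'
#' Exact Euclidean distance from each foreground sample to the nearest
#' background sample, with anisotropic spacing. The volume border counts as
#' background (objects cut by the border get small distances there).
#'
#' @param mask logical 2D or 3D array.
#' @param spacing per-axis sample spacing in micrometers (matching
#'   `dim(mask)` order).
#' @return numeric array of distances (micrometers), 0 on background.
#' @export
edt3d <- function(mask, spacing = c(1, 1, 1)) {
  d0 <- dim(mask)
  m <- as_array3(mask)
  spacing <- rep(spacing, length.out = 3)
  if (length(d0) == 2) spacing <- c(spacing[1:2], 1)
  d <- dim(m)
  # pad with one background layer so the border is a boundary
  mp <- array(FALSE, d + 2)
  mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  out <- .edt3d_cpp(as.logical(mp), dim(mp), spacing)
  out <- array(out, dim(mp))[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  dim(out) <- d0
  out
}

#' Skeleton graph of sub-voxel centerline points
#'
#' @param nodes n x 3 matrix of physical `(x, y, z)` points, micrometers.
#' @param edges m x 2 integer matrix of node index pairs (undirected).
#' @return object of class `skeleton_graph` with `nodes`, `edges`,
#'   `lengths` (per-edge Euclidean length) and a cached igraph.
#' @export
skeleton_graph <- function(nodes, edges) {
  nodes <- as_matrix3(nodes)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    stop("skeleton graph must not contain self-loops")
  len <- if (nrow(edges)) {
    sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                    nodes[edges[, 2], , drop = FALSE])^2))
  } else numeric(0)
  if (any(len <= 0)) stop("skeleton edges must have positive length")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(nodes) - igraph::vcount(g)))
  structure(list(nodes = nodes, edges = edges, lengths = len, graph = g),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges, total length %.3f um\n",
              nrow(x$nodes), nrow(x$edges), sum(x$lengths)))
  invisible(x)
}

#' @rdname skeleton_graph
#' @param graph a `skeleton_graph`.
#' @export
node_degrees <- function(graph) igraph::degree(graph$graph)

# T-field gradient descent with 4th-order (RK4) stepping; physical coords.
backtrace_path <- function(Tf, spacing, start_zyx, source_zyx, step_um,
                           max_steps = 200000L) {
  ip <- function(zyx) interp_trilinear(Tf, zyx, clamp = TRUE)$values
  grad_at <- function(zyx) {
    h <- 0.5
    sh <- function(dz, dy, dx) matrix(c(dz, dy, dx), nrow(zyx), 3, TRUE)
    gz <- (ip(zyx + sh(h, 0, 0)) - ip(zyx - sh(h, 0, 0))) / (2 * h * spacing[1])
    gy <- (ip(zyx + sh(0, h, 0)) - ip(zyx - sh(0, h, 0))) / (2 * h * spacing[2])
    gx <- (ip(zyx + sh(0, 0, h)) - ip(zyx - sh(0, 0, h))) / (2 * h * spacing[3])
    cbind(gz, gy, gx)
  }
  dir_at <- function(zyx) {
    g <- grad_at(zyx)
    n <- sqrt(rowSums(g^2))
    if (n < 1e-12) return(NULL)
    -g / n
  }
  to_um <- function(zyx) zyx * spacing # per-axis scale, origin 0
  src_um <- to_um(matrix(source_zyx, 1))
  cur <- matrix(start_zyx, 1)
  path <- list(cur)
  step_vox <- function(zyx, d_um) {
    matrix(d_um / spacing, 1) # convert a physical step to index steps
  }
  tol <- max(spacing) # stop within one voxel of the source
  for (k in seq_len(max_steps)) {
    if (sqrt(sum((to_um(cur) - src_um)^2)) <= tol) break
    k1 <- dir_at(cur); if (is.null(k1)) break
    k2 <- dir_at(cur + step_vox(cur, step_um / 2 * k1[1, ]))
    if (is.null(k2)) k2 <- k1
    k3 <- dir_at(cur + step_vox(cur, step_um / 2 * k2[1, ]))
    if (is.null(k3)) k3 <- k2
    k4 <- dir_at(cur + step_vox(cur, step_um * k3[1, ]))
    if (is.null(k4)) k4 <- k3
    d <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    d <- d / max(sqrt(sum(d^2)), 1e-12)
    nxt <- cur + step_vox(cur, step_um * d[1, ])
    # bail out if the descent stalls (flat/noisy arrival field)
    if (sqrt(sum(((nxt - cur) * spacing)^2)) < step_um * 1e-3) break
    cur <- nxt
    path[[length(path) + 1]] <- cur
  }
  zyx <- do.call(rbind, path)
  cbind(x = zyx[, 3] * spacing[3], y = zyx[, 2] * spacing[2],
        z = zyx[, 1] * spacing[1])
}

# thin a dense polyline to a minimum node spacing, keeping the endpoints
thin_polyline <- function(p, min_spacing) {
  if (nrow(p) < 2) return(p)
  keep <- 1L
  last <- p[1, ]
  for (i in 2:nrow(p)) {
    if (sqrt(sum((p[i, ] - last)^2)) >= min_spacing) {
      keep <- c(keep, i)
      last <- p[i, ]
    }
  }
  if (keep[length(keep)] != nrow(p)) keep <- c(keep, nrow(p))
  p[keep, , drop = FALSE]
}

#' Sub-voxel 3D centerline by fast marching
#'
#' Per 26-connected foreground component: a centeredness-weighted
#' fast-marching arrival-time solve (speed = normalized distance-to-boundary
#' raised to `speed_power`) is seeded at the deepest voxel. Path endpoints
#' are detected on uniform-speed (geodesic) arrival times with a double
#' sweep - the farthest point from the seed is one tip, and the geodesic
#' field re-solved from that tip exposes all others as local maxima - then
#' non-maximum-suppressed and snapped onto the distance ridge. Each endpoint
#' is traced back to the seed by RK4 gradient descent on the weighted
#' arrival time with sub-voxel steps. Traced paths are merged into a graph,
#' fusing points closer than half a voxel, so side paths attach where they
#' meet the main path. Components whose geodesic extent does not exceed
#' three times their depth (compact blobs) collapse to a single node.
#'
#' @param mask logical 3D array (foreground = fiber).
#' @param spacing voxel spacing `(z, y, x)` micrometers.
#' @param min_component_voxels components smaller than this are skipped with
#'   a warning.
#' @param endpoint_frac endpoint detection threshold as a fraction of the
#'   component's maximum arrival time.
#' @param nms_radius_vox non-maximum suppression radius for endpoints,
#'   voxels.
#' @param step_vox backtrace step, voxels.
#' @param fuse_radius_vox node fusing radius, voxels.
#' @param speed_power exponent on the normalized distance field used as the
#'   marching speed; larger values keep minimal paths from cutting corners
#'   inside bends.
#' @return a [skeleton_graph()] (possibly with several components); node
#'   coordinates are physical micrometers with voxel `(0,0,0)` at the origin.
#' @export
fast_marching_centerline <- function(mask, spacing = c(1, 1, 1),
                                     min_component_voxels = 27,
                                     endpoint_frac = 0.25,
                                     nms_radius_vox = 3,
                                     step_vox = 0.25,
                                     fuse_radius_vox = 0.5,
                                     speed_power = 4) {
  if (!any(mask)) stop("empty mask: no foreground to skeletonize")
  spacing <- rep(spacing, length.out = 3)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  nodes <- matrix(0, 0, 3)
  edges <- matrix(0L, 0, 2)
  fuse_um <- fuse_radius_vox * min(spacing)
  D <- edt3d(mask, spacing)
  for (comp in which(sizes > 0)) {
    if (sizes[comp] < min_component_voxels) {
      warning("skipping component of ", sizes[comp], " voxels (< ",
              min_component_voxels, ")")
      next
    }
    cm <- lab == comp
    Dc <- ifelse(cm, D, 0)
    maxD <- max(Dc)
    src <- which.max(Dc)
    src_idx0 <- arrayInd(src, dim(mask)) - 1
    src_um <- c(src_idx0[1, 3] * spacing[3], src_idx0[1, 2] * spacing[2],
                src_idx0[1, 1] * spacing[1])
    # Endpoint detection uses geodesic (uniform-speed) arrival times with a
    # double sweep: the deepest voxel can sit anywhere along the object (the
    # depth field ties along the whole axis), so a tip right next to it would
    # fall below any global threshold. The farthest point v1 from the deepest
    # voxel is one true tip; the geodesic field solved FROM v1 has all other
    # tips as strong maxima, and v1 joins the endpoint set itself. The
    # centeredness-weighted time diverges at every boundary bump and is
    # useless for endpoint detection; it is what the paths are traced on.
    geo <- as.numeric(ifelse(cm, 1, 0))
    Tg0 <- array(.fmm3d_cpp(geo, dim(mask), spacing, as.integer(src)),
                 dim(mask))
    Tg0[!cm | !is.finite(Tg0)] <- -Inf
    v1 <- which.max(Tg0)
    Tg <- array(.fmm3d_cpp(geo, dim(mask), spacing, as.integer(v1)),
                dim(mask))
    Tmax <- max(Tg[cm & is.finite(Tg)])
    if (Tmax <= 3 * maxD) { # compact blob, no elongation: a single node
      nodes <- rbind(nodes, src_um)
      next
    }
    speed <- ifelse(cm, pmax((Dc / maxD)^speed_power, 1e-4), 0)
    T <- .fmm3d_cpp(as.numeric(speed), dim(mask), spacing, as.integer(src))
    T <- array(T, dim(mask))
    # endpoints: local maxima of the v1-seeded geodesic arrival time
    Tn <- ifelse(cm & is.finite(Tg), Tg, -Inf)
    nbr_max <- array(-Inf, dim(Tn))
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      sh <- shift_along_axis(shift_along_axis(
        shift_along_axis(Tn, 1, dz), 2, dy), 3, dx)
      nbr_max <- pmax(nbr_max, sh)
    }
    cand <- unique(c(which(Tn >= nbr_max & Tn >= endpoint_frac * Tmax & cm),
                     v1))
    src_idx <- arrayInd(src, dim(mask)) - 1
    if (length(cand)) {
      ord <- cand[order(Tg[cand], decreasing = TRUE)]
      pos <- (arrayInd(ord, dim(mask)) - 1) * matrix(spacing, length(ord), 3, TRUE)
      keep <- integer(0)
      nms_um <- nms_radius_vox * min(spacing)
      for (i in seq_along(ord)) {
        if (!length(keep) ||
            min(sqrt(rowSums((pos[keep, , drop = FALSE] -
                                matrix(pos[i, ], length(keep), 3, TRUE))^2))) >
            nms_um) {
          keep <- c(keep, i)
        }
      }
      ends <- ord[keep]
      # snap each endpoint from the arrival-time maximum (often on the end-cap
      # rim) onto the nearby distance-field ridge, i.e. the axis
      rr <- max(1L, ceiling(maxD / min(spacing)))
      d <- dim(mask)
      ends <- unique(vapply(ends, function(e) {
        ei <- arrayInd(e, d)
        zr <- max(1, ei[1] - rr):min(d[1], ei[1] + rr)
        yr <- max(1, ei[2] - rr):min(d[2], ei[2] + rr)
        xr <- max(1, ei[3] - rr):min(d[3], ei[3] + rr)
        sub <- Dc[zr, yr, xr, drop = FALSE]
        # deep enough to sit on the medial ridge, then as far out as the tip
        # allows: keeps the trace anchored at the very end of the object even
        # when a rough cap pulls the depth maximum inward
        # among ridge-deep voxels take those geodesically near the very tip,
        # then the deepest of them: anchored at the object's end yet on-axis
        cands <- which(sub >= 0.5 * max(sub))
        b <- arrayInd(cands, dim(sub))
        # v1 is the source of Tg, so its own outwardness is read from Tg0
        tip_field <- if (e == v1) Tg0 else Tg
        tg_c <- tip_field[cbind(zr[b[, 1]], yr[b[, 2]], xr[b[, 3]])]
        near_tip <- tg_c >= max(tg_c) - 0.5 * maxD
        cands <- cands[near_tip]
        b <- b[near_tip, , drop = FALSE]
        b <- b[which.max(sub[cands]), ]
        as.integer((xr[b[3]] - 1) * d[1] * d[2] + (yr[b[2]] - 1) * d[1] +
                     zr[b[1]])
      }, integer(1)))
      ends <- ends[order(Tg[ends], decreasing = TRUE)]
      # several rim maxima of one end cap can recenter to distinct ridge
      # voxels up to the recentering radius apart; suppress those duplicates
      if (length(ends) > 1) {
        pos <- (arrayInd(ends, d) - 1) *
          matrix(spacing, length(ends), 3, TRUE)
        keep <- integer(0)
        nms_um <- (nms_radius_vox + rr) * min(spacing)
        for (i in seq_along(ends)) {
          if (!length(keep) ||
              min(sqrt(rowSums((pos[keep, , drop = FALSE] -
                                  matrix(pos[i, ], length(keep), 3,
                                         TRUE))^2))) > nms_um) {
            keep <- c(keep, i)
          }
        }
        ends <- ends[keep]
      }
    } else {
      ends <- integer(0)
    }
    Tc_max <- max(T[cm & is.finite(T)])
    Tf <- ifelse(cm & is.finite(T), T, Tc_max * 1.2)
    if (!length(ends)) { # no detectable tips: a single node
      nodes <- rbind(nodes, src_um)
      next
    }
    comp_nodes <- matrix(0, 0, 3)
    comp_edges <- matrix(0L, 0, 2)
    base <- nrow(nodes)
    for (e in seq_along(ends)) {
      st <- arrayInd(ends[e], dim(mask)) - 1
      p <- backtrace_path(Tf, spacing, st[1, ], src_idx[1, ],
                          step_um = step_vox * min(spacing))
      p <- thin_polyline(p, 0.5 * min(spacing))
      if (e == 1) {
        p <- thin_polyline(p, 0.25 * min(spacing))
        if (nrow(p) > 1) { # drop coincident consecutive points
          seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                                 p[-nrow(p), , drop = FALSE])^2))
          p <- p[c(TRUE, seg > 1e-9), , drop = FALSE]
        }
        comp_nodes <- p
        if (nrow(p) > 1) {
          comp_edges <- cbind(seq_len(nrow(p) - 1), seq_len(nrow(p) - 1) + 1)
        }
      } else {
        # truncate at the first point near the accepted set, then connect
        dmin <- function(q) min(sqrt(rowSums((comp_nodes -
          matrix(q, nrow(comp_nodes), 3, TRUE))^2)))
        cut <- nrow(p)
        for (i in seq_len(nrow(p))) {
          if (dmin(p[i, ]) <= fuse_um) { cut <- i; break }
        }
        near <- which.min(sqrt(rowSums((comp_nodes -
          matrix(p[cut, ], nrow(comp_nodes), 3, TRUE))^2)))
        newn <- p[seq_len(cut - 1), , drop = FALSE]
        if (nrow(newn) > 1) {
          seg <- sqrt(rowSums((newn[-1, , drop = FALSE] -
                                 newn[-nrow(newn), , drop = FALSE])^2))
          newn <- newn[c(TRUE, seg > 1e-9), , drop = FALSE]
        }
        while (nrow(newn) &&
               sqrt(sum((newn[nrow(newn), ] - comp_nodes[near, ])^2)) < 1e-9) {
          newn <- newn[-nrow(newn), , drop = FALSE]
        }
        if (nrow(newn)) {
          off <- nrow(comp_nodes)
          comp_nodes <- rbind(comp_nodes, newn)
          if (nrow(newn) > 1) {
            comp_edges <- rbind(comp_edges,
                                cbind(off + seq_len(nrow(newn) - 1),
                                      off + seq_len(nrow(newn) - 1) + 1))
          }
          comp_edges <- rbind(comp_edges, c(off + nrow(newn), near))
        }
      }
    }
    nodes <- rbind(nodes, comp_nodes)
    if (nrow(comp_edges)) edges <- rbind(edges, comp_edges + base)
  }
  if (!nrow(nodes)) stop("no component was large enough to skeletonize")
  rownames(nodes) <- NULL
  skeleton_graph(nodes, edges)
}

#' Order skeleton nodes into coordinate lists
#'
#' Each connected component is traversed depth-first from a degree-1 node
#' (or, absent one, from the node farthest from the component centroid);
#' every node appears exactly once.
#'
#' @param graph a [skeleton_graph()].
#' @return list of n x 3 coordinate matrices, one per component, in
#'   traversal order.
#' @export
order_skeleton <- function(graph) {
  if (!nrow(graph$nodes)) stop("empty skeleton graph")
  g <- graph$graph
  comps <- igraph::components(g)
  out <- list()
  for (cid in seq_len(comps$no)) {
    vids <- which(comps$membership == cid)
    sub <- igraph::induced_subgraph(g, vids)
    deg <- igraph::degree(sub)
    pts <- graph$nodes[vids, , drop = FALSE]
    if (any(deg == 1)) {
      root <- which(deg == 1)[1]
    } else if (length(vids) == 1) {
      root <- 1L
    } else {
      ctr <- colMeans(pts)
      root <- which.max(rowSums((pts - matrix(ctr, nrow(pts), 3, TRUE))^2))
    }
    ord <- as.integer(igraph::dfs(sub, root = root)$order)
    out[[cid]] <- pts[ord, , drop = FALSE]
  }
  out
}

#' Trim a skeleton to its main trunk
#'
#' Returns the maximum-total-length simple path through the skeleton (the
#' weighted tree diameter); all side branches are discarded. Graphs with
#' cycles are first reduced to a maximum-total-length spanning tree, with a
#' warning.
#'
#' @param graph a connected [skeleton_graph()].
#' @return a [curve3d()] along the trunk.
#' @export
trim_to_trunk <- function(graph) {
  g <- graph$graph
  igraph::E(g)$weight <- graph$lengths
  if (igraph::components(g)$no != 1)
    stop("trim_to_trunk() needs a connected graph; trim per component")
  if (igraph::ecount(g) >= igraph::vcount(g)) {
    warning("skeleton graph contains cycles; using a maximum spanning tree")
    g <- igraph::mst(g, weights = -igraph::E(g)$weight)
    igraph::E(g)$weight <- abs(igraph::E(g)$weight)
  }
  d1 <- igraph::distances(g, v = 1)
  v1 <- which.max(d1)
  d2 <- igraph::distances(g, v = v1)
  v2 <- which.max(d2)
  path <- igraph::shortest_paths(g, from = v1, to = v2)$vpath[[1]]
  curve3d(graph$nodes[as.integer(path), , drop = FALSE])
}

#' Resample a curve with a cubic spline
#'
#' Fits an interpolating cubic spline per coordinate against cumulative
#' chord length and evaluates it at `factor` times the original point count,
#' uniformly in chord length. Endpoints are preserved.
#'
#' @param curve a [curve3d()] with at least 4 points.
#' @param factor integer >= 1; the output has `factor * nrow(curve)` points.
#' @return resampled [curve3d()].
#' @export
resample_spline <- function(curve, factor = 3L) {
  if (factor < 1) stop("factor must be >= 1")
  p <- unclass(curve)
  if (nrow(p) < 4) stop("cubic resampling needs at least 4 points")
  s <- attr(curve, "arc_length")
  sout <- seq(0, s[length(s)], length.out = as.integer(factor) * nrow(p))
  out <- vapply(1:3, function(j)
    stats::spline(s, p[, j], xout = sout, method = "natural")$y,
    numeric(length(sout)))
  curve3d(out)
}
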