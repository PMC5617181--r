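# Shared fixture builders (all generated in code; no binary fixtures).

# solid tube along x: radius r voxels, centered at (z0, y0) in 1-based index
# space, spanning x in [x0, x1]
tube_mask <- function(dims, r, z0, y0, x0, x1) {
  m <- array(FALSE, dims)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  inside <- (idx[, 1] - z0)^2 + (idx[, 2] - y0)^2 <= r^2 &
    idx[, 3] >= x0 & idx[, 3] <= x1
  m[idx[inside, , drop = FALSE]] <- TRUE
  m
}

# solid ball, 1-based index center
ball_mask <- function(dims, r, ctr) {
  m <- array(FALSE, dims)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  inside <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
    (idx[, 3] - ctr[3])^2 <= r^2
  m[idx[inside, , drop = FALSE]] <- TRUE
  m
}

# analytic tube painted from a polyline of 1-based (z, y, x) index points
polyline_tube_mask <- function(dims, pts_zyx, r, n_samp = 400) {
  m <- array(FALSE, dims)
  t <- seq(0, 1, length.out = n_samp)
  seg <- nrow(pts_zyx) - 1
  st <- pmin(floor(t * seg) + 1, seg)
  f <- t * seg - (st - 1)
  ctr <- pts_zyx[st, , drop = FALSE] * (1 - f) +
    pts_zyx[st + 1, , drop = FALSE] * f
  for (i in seq_len(n_samp)) {
    c0 <- ctr[i, ]
    zr <- max(1, floor(c0[1] - r)):min(dims[1], ceiling(c0[1] + r))
    yr <- max(1, floor(c0[2] - r)):min(dims[2], ceiling(c0[2] + r))
    xr <- max(1, floor(c0[3] - r)):min(dims[3], ceiling(c0[3] + r))
    d2 <- outer(outer((zr - c0[1])^2, (yr - c0[2])^2, "+"), (xr - c0[3])^2, "+")
    m[zr, yr, xr] <- m[zr, yr, xr] | (d2 <= r^2)
  }
  m
}

# rough initial centerline for a phantom: downsampled truth plus a fixed
# sub-radius offset (stands in for a hand-drawn curve)
rough_centerline <- function(phantom, n = 15, offset = c(0.3, -0.25, 0.2)) {
  tcl <- unclass(phantom$truth$centerline)
  pick <- round(seq(1, nrow(tcl), length.out = n))
  curve3d(tcl[pick, ] + matrix(offset, n, 3, TRUE))
}

expect_unit_rows <- function(m, tol = 1e-9) {
  expect_true(all(abs(sqrt(rowSums(m^2)) - 1) < tol))
}

# exhaustive longest-path oracle on a tree (node pairs x unique tree paths)
brute_longest_path <- function(nodes, edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  w <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                       nodes[edges[, 2], , drop = FALSE])^2))
  igraph::E(g)$weight <- w
  n <- nrow(nodes)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- as.numeric(igraph::distances(g, v = i, to = j))
    if (d > best) best <- d
  }
  best
}

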