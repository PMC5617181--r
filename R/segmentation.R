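as_array3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a 2D or 3D array")
  if (length(d) == 2) dim(x) <- c(d, 1L)
  x
}

# Kapur maximum-entropy threshold from a 256-bin histogram: picks the bin
# boundary maximizing the summed Shannon entropies of the two classes.
threshold_kapur <- function(x, levels = 256) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(pmin(findInterval(x, br, all.inside = TRUE), levels), levels)
  p <- h / sum(h)
  P <- cumsum(p)
  ent <- cumsum(ifelse(p > 0, -p * log(p), 0))
  tot <- ent[levels]
  k <- seq_len(levels - 1)
  ok <- P[k] > 0 & P[k] < 1
  H <- rep(-Inf, levels - 1)
  H[ok] <- log(P[k][ok] * (1 - P[k][ok])) + ent[k][ok] / P[k][ok] +
    (tot - ent[k][ok]) / (1 - P[k][ok])
  br[which.max(H) + 1]
}

#' Binarize an intensity image or volume
#'
#' Thresholds computed from a 256-bin histogram of the input; foreground is
#' `intensity > threshold`.
#'
#' @param image 2D or 3D numeric array.
#' @param method `"otsu"` (between-class variance), `"isodata"`
#'   (Ridler-Calvard class-mean midpoint; places the boundary at the
#'   half-contrast level of a blurred edge), `"max_entropy"` (Kapur) or
#'   `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return logical array of the input shape with a `threshold` attribute.
#' @export
binarize <- function(image, method = c("otsu", "isodata", "max_entropy",
                                       "fixed"),
                     level = NULL) {
  method <- match.arg(method)
  if (length(image) == 0) stop("empty image")
  rng <- range(image)
  if (method != "fixed" && rng[1] == rng[2])
    stop("constant image: no ", method, " threshold exists")
  thr <- switch(method,
    otsu = {
      xn <- (image - rng[1]) / (rng[2] - rng[1])
      t01 <- EBImage::otsu(EBImage::Image(as.numeric(xn)),
                           range = c(0, 1), levels = 256)
      rng[1] + t01 * (rng[2] - rng[1])
    },
    isodata = {
      t <- mean(rng)
      for (it in 1:100) {
        lo <- image[image <= t]
        hi <- image[image > t]
        if (!length(lo) || !length(hi)) break
        t2 <- (mean(lo) + mean(hi)) / 2
        if (abs(t2 - t) < 1e-9 * diff(rng)) break
        t <- t2
      }
      t
    },
    max_entropy = threshold_kapur(image),
    fixed = {
      if (is.null(level)) stop("fixed method requires a level")
      level
    })
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Morphological cleanup of a binary mask
#'
#' Closing with a Euclidean ball of the given radius (in samples), then
#' removal of connected components below a size floor. Connectivity is
#' 26-wise in 3D and 8-wise in 2D.
#'
#' @param mask logical 2D or 3D array.
#' @param min_component_size minimum component size kept, in samples.
#' @param closing_radius closing ball radius in samples (0 skips closing).
#' @return cleaned logical array, same shape.
#' @export
clean_mask <- function(mask, min_component_size = 0, closing_radius = 0) {
  if (min_component_size < 0 || closing_radius < 0)
    stop("cleanup parameters must be >= 0")
  d0 <- dim(mask)
  m <- as_array3(mask)
  if (closing_radius > 0) {
    # dilation then erosion via distance fields (exact Euclidean ball)
    dist_to_fg <- edt3d(!m, spacing = c(1, 1, 1))
    dil <- dist_to_fg <= closing_radius
    dist_to_bg <- edt3d(dil, spacing = c(1, 1, 1))
    m <- dil & dist_to_bg > closing_radius
    # closing never removes original foreground
    m <- m | as_array3(mask)
  }
  if (min_component_size > 0 && any(m)) {
    lab <- label_components(m)
    keep <- which(tabulate(lab[lab > 0]) >= min_component_size)
    m <- array(lab %in% keep, dim(m))
  }
  dim(m) <- d0
  m
}

#' Tolerance-based region growing inside a box
#'
#' Connected set of samples containing the seed whose intensity differs from
#' the seed intensity by at most `tolerance`, clipped to `roi`.
#'
#' @param image 2D or 3D numeric array.
#' @param seed index vector (1-based, array coordinates) of the seed sample.
#' @param roi list with `lo` and `hi` index vectors bounding the box
#'   (inclusive), or `NULL` for the whole image.
#' @param tolerance maximum absolute intensity difference from the seed.
#' @return logical array of the input shape.
#' @export
region_grow <- function(image, seed, roi = NULL, tolerance = 0) {
  d0 <- dim(image)
  a <- as_array3(image)
  d <- dim(a)
  seed <- as.integer(rep(seed, length.out = length(d0))[seq_along(d0)])
  if (length(d0) == 2) seed <- c(seed, 1L)
  if (any(seed < 1) || any(seed > d)) stop("seed outside the image")
  if (is.null(roi)) {
    roi <- list(lo = c(1, 1, 1), hi = d)
  } else {
    roi <- list(lo = c(rep(roi$lo, length.out = length(d0)),
                       1)[1:3],
                hi = c(rep(roi$hi, length.out = length(d0)), 1)[1:3])
    if (any(roi$lo < 1) || any(roi$hi > d)) stop("roi outside the image")
    if (any(seed < roi$lo) || any(seed > roi$hi)) stop("seed outside the roi")
  }
  inroi <- array(FALSE, d)
  inroi[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2], roi$lo[3]:roi$hi[3]] <- TRUE
  sval <- a[seed[1], seed[2], seed[3]]
  cand <- inroi & abs(a - sval) <= tolerance
  lab <- label_components(cand)
  out <- array(lab == lab[seed[1], seed[2], seed[3]], d)
  dim(out) <- d0
  out
}

#' Connected-component labels (26-connectivity; 8-connectivity in 2D)
#'
#' @param mask logical 2D or 3D array.
#' @return integer array of the input shape; 0 = background.
#' @export
label_components <- function(mask) {
  d0 <- dim(mask)
  m <- as_array3(mask)
  lab <- .label_cc_cpp(as.logical(m), dim(m))
  dim(lab) <- d0
  lab
}

# one Zhang-Suen thinning subiteration; m is logical matrix padded by callers
zs_subiter <- function(m, step) {
  n <- nrow(m); p <- ncol(m)
  sh <- function(dr, dc) {
    r <- pmin(pmax(seq_len(n) + dr, 1L), n)
    c <- pmin(pmax(seq_len(p) + dc, 1L), p)
    m[r, c]
  }
  # neighbors P2..P9 clockwise from north; matrix rows = y (north = row-1)
  P2 <- sh(-1, 0); P3 <- sh(-1, 1); P4 <- sh(0, 1); P5 <- sh(1, 1)
  P6 <- sh(1, 0); P7 <- sh(1, -1); P8 <- sh(0, -1); P9 <- sh(-1, -1)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
    (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
  if (step == 1) {
    cond <- m & B >= 2 & B <= 6 & A == 1 &
      !(P2 & P4 & P6) & !(P4 & P6 & P8)
  } else {
    cond <- m & B >= 2 & B <= 6 & A == 1 &
      !(P2 & P4 & P8) & !(P2 & P6 & P8)
  }
  m & !cond
}

#' 2D skeleton by morphological thinning
#'
#' Zhang-Suen thinning to a one-pixel-wide medial skeleton, followed by
#' traversal of each 8-connected skeleton component into an ordered pixel
#' chain (endpoint to endpoint where endpoints exist).
#'
#' @param mask logical matrix.
#' @return list of chains, each an m x 2 matrix of `(row, col)` pixel
#'   coordinates in traversal order. Empty mask gives an empty list.
#' @export
skeletonize_2d <- function(mask) {
  if (length(dim(mask)) != 2) stop("skeletonize_2d expects a 2D mask")
  if (!any(mask)) return(list())
  m <- mask
  repeat {
    m1 <- zs_subiter(m, 1)
    m2 <- zs_subiter(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  # small blobs (e.g. a solid 2x2 square) can vanish entirely under
  # Zhang-Suen; represent each lost component by its most central pixel
  lab0 <- label_components(mask)
  for (l in seq_len(max(lab0))) {
    if (!any(m[lab0 == l])) {
      px <- which(lab0 == l, arr.ind = TRUE)
      ctr <- colMeans(px)
      best <- which.min((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
      m[px[best, 1], px[best, 2]] <- TRUE
    }
  }
  lab <- label_components(m)
  chains <- list()
  for (l in sort(unique(lab[lab > 0]))) {
    px <- which(lab == l, arr.ind = TRUE)
    chains[[length(chains) + 1]] <- order_pixel_chain(px)
  }
  chains
}

# order the pixels of one thin 8-connected component into a chain
order_pixel_chain <- function(px) {
  n <- nrow(px)
  if (n == 1) return(px)
  dmat <- as.matrix(dist(px, method = "maximum"))
  adj <- dmat <= 1 & dmat > 0
  deg <- rowSums(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- which(deg == 1)
  if (length(ends) >= 2) {
    # endpoint-to-endpoint traversal along the farthest endpoint pair
    dd <- igraph::distances(g, v = ends, to = ends)
    pick <- which(dd == max(dd[is.finite(dd)]), arr.ind = TRUE)[1, ]
    path <- igraph::shortest_paths(g, from = ends[pick[1]],
                                   to = ends[pick[2]])$vpath[[1]]
  } else {
    path <- igraph::dfs(g, root = 1)$order
  }
  px[as.integer(path), , drop = FALSE]
}

#' Join skeleton chains across gaps with a spline
#'
#' Orders point chains end-to-end by greedy nearest-endpoint pairing, then
#' fits a cubic smoothing spline (per coordinate against cumulative chord
#' length) through all points and evaluates it densely, bridging the gaps.
#'
#' @param chains list of m x d point matrices (d = 2 or 3), coordinates in
#'   micrometers.
#' @param max_gap largest endpoint-to-endpoint gap that may be bridged,
#'   micrometers; a larger gap is an error naming the offending endpoints.
#' @param spacing output sample spacing (micrometers); default median input
#'   point spacing.
#' @param spar smoothing parameter passed to [stats::smooth.spline()]
#'   (`NULL` = light fixed smoothing tied to the chord parameterization).
#' @return single ordered point matrix (n x d) along the joined curve.
#' @export
fill_gaps_spline <- function(chains, max_gap, spacing = NULL, spar = NULL) {
  if (!length(chains)) stop("no chains supplied")
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    storage.mode(ch) <- "double"
    ch
  })
  dims <- unique(vapply(chains, ncol, 1L))
  if (length(dims) != 1) stop("chains mix 2D and 3D points")
  # greedy nearest-endpoint chaining
  cur <- chains[[1]]
  rest <- chains[-1]
  while (length(rest)) {
    ce <- rbind(cur[1, ], cur[nrow(cur), ])
    best <- NULL
    for (k in seq_along(rest)) {
      re <- rbind(rest[[k]][1, ], rest[[k]][nrow(rest[[k]]), ])
      for (i in 1:2) for (j in 1:2) {
        gap <- sqrt(sum((ce[i, ] - re[j, ])^2))
        if (is.null(best) || gap < best$gap) best <- list(k = k, i = i, j = j, gap = gap)
      }
    }
    if (best$gap > max_gap) {
      stop(sprintf(
        "gap of %.3f um exceeds max_gap = %.3f um between endpoints (%s) and (%s)",
        best$gap, max_gap,
        paste(signif(if (best$i == 1) cur[1, ] else cur[nrow(cur), ], 5), collapse = ", "),
        paste(signif(if (best$j == 1) rest[[best$k]][1, ]
                     else rest[[best$k]][nrow(rest[[best$k]]), ], 5), collapse = ", ")))
    }
    nxt <- rest[[best$k]]
    if (best$j == 2) nxt <- nxt[rev(seq_len(nrow(nxt))), , drop = FALSE]
    if (best$i == 1) cur <- rbind(nxt[rev(seq_len(nrow(nxt))), , drop = FALSE], cur)
    else cur <- rbind(cur, nxt)
    rest <- rest[-best$k]
  }
  # drop duplicated consecutive points, parameterize by chord length
  seg <- sqrt(rowSums((cur[-1, , drop = FALSE] -
                         cur[-nrow(cur), , drop = FALSE])^2))
  cur <- cur[c(TRUE, seg > 1e-9), , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums((cur[-1, , drop = FALSE] -
                                   cur[-nrow(cur), , drop = FALSE])^2))))
  if (is.null(spacing)) spacing <- max(median(diff(s)), 1e-6)
  sout <- seq(0, s[length(s)], by = spacing)
  if (s[length(s)] - sout[length(sout)] > 1e-6 * spacing)
    sout <- c(sout, s[length(s)])
  out <- matrix(0, length(sout), ncol(cur))
  for (j in seq_len(ncol(cur))) {
    fit <- if (nrow(cur) >= 10) {
      stats::smooth.spline(s, cur[, j],
                           spar = spar %||% 0.3, keep.data = FALSE)
    } else {
      NULL
    }
    if (is.null(fit)) {
      out[, j] <- stats::spline(s, cur[, j], xout = sout,
                                method = "natural")$y
    } else {
      out[, j] <- stats::predict(fit, sout)$y
    }
  }
  out
}
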