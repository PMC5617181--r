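test_that("the distance transform is exact and border-aware", {
  a <- array(TRUE, c(9, 9, 9))
  d <- edt3d(a)
  expect_equal(d[5, 5, 5], 5) # center to the padded border
  expect_equal(d[1, 5, 5], 1)
  m <- array(FALSE, c(7, 7, 7))
  m[4, 4, 4] <- TRUE
  expect_equal(edt3d(m)[4, 4, 4], 1)
  # anisotropic spacing
  m2 <- array(TRUE, c(3, 21, 21))
  expect_equal(edt3d(m2, c(0.1, 1, 1))[2, 11, 11], 0.2)
})

test_that("straight tubes give a single sub-voxel accurate centerline", {
  m <- tube_mask(c(20, 20, 50), r = 3, z0 = 10.5, y0 = 10.5, x0 = 3, x1 = 42)
  g <- fast_marching_centerline(m, c(1, 1, 1))
  deg <- node_degrees(g)
  expect_equal(sum(deg > 2), 0) # single path, no spurious branches
  n <- g$nodes
  rms <- sqrt(mean((n[, 2] - 9.5)^2 + (n[, 3] - 9.5)^2))
  expect_lte(rms, 0.5)
  expect_gt(diff(range(n[, 1])), 30) # spans most of the 40-voxel tube
})

test_that("a solid ball collapses to a point-like skeleton", {
  b <- ball_mask(c(15, 15, 15), r = 5, ctr = c(8, 8, 8))
  g <- fast_marching_centerline(b, c(1, 1, 1))
  expect_lte(nrow(g$nodes), 5)
  expect_lt(max(sqrt(rowSums((g$nodes -
    matrix(7, nrow(g$nodes), 3))^2))), 2)
})

test_that("a Y junction yields exactly one degree-3 node at the meeting point", {
  pts <- rbind(c(12, 20, 3), c(12, 20, 22))
  ym <- polyline_tube_mask(c(24, 40, 40), pts, r = 3)
  ym <- ym | polyline_tube_mask(c(24, 40, 40), rbind(c(12, 20, 22), c(12, 35, 35)), r = 3)
  ym <- ym | polyline_tube_mask(c(24, 40, 40), rbind(c(12, 20, 22), c(12, 6, 36)), r = 3)
  g <- fast_marching_centerline(ym, c(1, 1, 1))
  deg <- node_degrees(g)
  expect_equal(sum(deg == 3), 1)
  junction <- g$nodes[deg == 3, ]
  expect_lt(sqrt(sum((junction - c(21, 19, 11))^2)), 2)
})

test_that("small components are skipped with a warning; empty masks error", {
  expect_error(fast_marching_centerline(array(FALSE, c(5, 5, 5))), "empty")
  m <- tube_mask(c(16, 16, 40), r = 3, z0 = 8.5, y0 = 8.5, x0 = 3, x1 = 35)
  m[2, 2, 2] <- TRUE # 1-voxel speck
  expect_warning(g <- fast_marching_centerline(m, c(1, 1, 1)), "skipping")
  expect_gt(nrow(g$nodes), 10)
})

test_that("order_skeleton traverses components end to end exactly once", {
  # path graph with known order, supplied shuffled
  x <- seq(0, 9, length.out = 10)
  pts <- cbind(x, sin(x), 0)
  withr::local_seed(9)
  perm <- sample(10)
  edges <- cbind(match(1:9, perm), match(2:10, perm))
  g <- skeleton_graph(pts[perm, ], edges)
  ord <- order_skeleton(g)
  expect_length(ord, 1)
  got <- ord[[1]]
  expect_true(isTRUE(all.equal(got, pts, check.attributes = FALSE)) ||
                isTRUE(all.equal(got, pts[10:1, ], check.attributes = FALSE)))
  # permutation property: same multiset of nodes
  expect_equal(got[order(got[, 1]), ], pts[order(pts[, 1]), ],
               ignore_attr = TRUE)
  single <- skeleton_graph(matrix(c(1, 2, 3), 1), matrix(0L, 0, 2))
  expect_equal(order_skeleton(single)[[1]], matrix(c(1, 2, 3), 1),
               ignore_attr = TRUE)
})

test_that("trunk trimming keeps the maximum-length path", {
  # Y tree with arm lengths 10, 8, 3 from one junction
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 3))
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4))
  trunk <- trim_to_trunk(skeleton_graph(nodes, edges))
  expect_equal(total_length(trunk), 18)
  expect_equal(nrow(trunk), 3)
  # caterpillar: 50 um trunk with five 1 um spurs
  spine <- cbind(seq(0, 50, by = 5), 0, 0)
  nodes2 <- rbind(spine, cbind(seq(5, 45, by = 10), 1, 0))
  e_sp <- cbind(1:10, 2:11)
  e_spur <- cbind(match(seq(5, 45, by = 10), spine[, 1]), 12:16)
  g2 <- skeleton_graph(nodes2, rbind(e_sp, e_spur))
  t2 <- trim_to_trunk(g2)
  expect_equal(total_length(t2), 50)
  # path graph is returned unchanged
  pg <- skeleton_graph(spine, e_sp)
  expect_equal(total_length(trim_to_trunk(pg)), 50)
})

test_that("trunk trimming matches the exhaustive oracle on random trees", {
  withr::local_seed(2024)
  for (rep in 1:100) {
    n <- sample(4:15, 1)
    nodes <- matrix(runif(3 * n, 0, 10), n, 3)
    parent <- vapply(2:n, function(i) sample(i - 1, 1), integer(1))
    edges <- cbind(parent, 2:n)
    g <- skeleton_graph(nodes, edges)
    expect_equal(total_length(trim_to_trunk(g)),
                 brute_longest_path(nodes, edges), tolerance = 1e-9)
  }
})

test_that("graphs with cycles fall back to a spanning tree with a warning", {
  nodes <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(0, 5, 0))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  expect_warning(trunk <- trim_to_trunk(skeleton_graph(nodes, edges)),
                 "cycles")
  expect_equal(total_length(trunk), 15)
})

test_that("centerline nodes stay inside the dilated source mask", {
  m <- polyline_tube_mask(c(24, 30, 60),
                          rbind(c(12, 8, 4), c(12, 22, 30), c(12, 8, 56)),
                          r = 3.5)
  g <- fast_marching_centerline(m, c(1, 1, 1))
  dil <- edt3d(!m) <= 1.0001 # mask dilated by one voxel
  inside <- vapply(seq_len(nrow(g$nodes)), function(i) {
    zyx <- pmin(pmax(round(c(g$nodes[i, 3], g$nodes[i, 2], g$nodes[i, 1])) + 1,
                     1), dim(m))
    dil[zyx[1], zyx[2], zyx[3]]
  }, logical(1))
  expect_true(all(inside))
})
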