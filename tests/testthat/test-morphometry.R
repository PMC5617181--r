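test_that("waviness is arc length over chord, invariant to rigid motion", {
  line <- cbind(seq(0, 7, length.out = 13), 0, 0)
  expect_equal(waviness(line), 1.0)
  th <- seq(0, pi, by = pi / 180)
  half_circle <- cbind(cos(th), sin(th), 0)
  expect_equal(waviness(half_circle), pi / 2, tolerance = 1e-3)
  # sine over one period, A = lambda / (2 pi): quadrature oracle
  lam <- 4
  x <- seq(0, lam, length.out = 4001)
  sine <- cbind(x, lam / (2 * pi) * sin(2 * pi * x / lam), 0)
  oracle <- integrate(function(u) sqrt(1 + cos(2 * pi * u / lam)^2), 0, lam,
                      rel.tol = 1e-10)$value / lam
  expect_equal(waviness(sine), oracle, tolerance = 0.005)
  # rigid motion + uniform scaling invariance
  R <- rotation_about_axis(c(1, 2, 0.5), 33)
  moved <- 2.5 * sine %*% t(R) + matrix(c(4, -1, 9), nrow(sine), 3, TRUE)
  expect_equal(waviness(moved), waviness(sine), tolerance = 1e-9)
  expect_error(waviness(rbind(c(0, 0, 0), c(1, 1, 0), c(0, 0, 0))),
               "coincident")
})

test_that("tilt follows the z-range over XY chord definition", {
  flat <- cbind(seq(0, 5, length.out = 9), sin(1:9), 2) # constant z
  expect_equal(tilt(flat), 0)
  expect_equal(tilt(rbind(c(0, 0, 0), c(10, 0, 10))), 45)
  expect_equal(tilt(rbind(c(0, 0, 0), c(20, 0, 2))), atan(0.1) * 180 / pi)
  # invariance under z-rotation and translation
  cv <- cbind(seq(0, 8, length.out = 20), cos(1:20), seq(0, 1, length.out = 20))
  Rz <- rotation_about_axis(c(0, 0, 1), 71)
  moved <- cv %*% t(Rz) + matrix(c(3, 4, 5), 20, 3, TRUE)
  expect_equal(tilt(moved), tilt(cv), tolerance = 1e-9)
  expect_warning(t90 <- tilt(rbind(c(0, 0, 0), c(0, 0, 4))), "vertical")
  expect_equal(t90, 90)
})

test_that("meshes of analytic solids recover area and volume", {
  sp <- c(0.25, 0.25, 0.25)
  b <- ball_mask(c(48, 48, 48), r = 20, ctr = c(24, 24, 24)) # 5 um ball
  mesh <- mesh_from_mask(b, sp)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * 25) - 1), 0.05)
  tube <- tube_mask(c(40, 40, 180), r = 8, z0 = 20.5, y0 = 20.5,
                    x0 = 9, x1 = 169) # r = 2 um, length 40 um
  mt <- mesh_from_mask(tube, sp)
  expect_lt(abs(mesh_volume(mt) / (pi * 4 * 40) - 1), 0.05)
  # watertight: every edge shared by exactly two faces
  e <- rbind(mt$faces[, 1:2], mt$faces[, 2:3], mt$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  # zero smoothing iterations leave marching output untouched
  m0 <- mesh_from_mask(b, sp, smoothing_iters = 0)
  m1 <- smooth_mesh(m0, 0)
  expect_identical(m0$vertices, m1$vertices)
})

test_that("cross sections match analytic disk and oblique ellipse areas", {
  sp <- c(0.25, 0.25, 0.25)
  tube <- tube_mask(c(40, 40, 180), r = 8, z0 = 20.5, y0 = 20.5,
                    x0 = 9, x1 = 169)
  mesh <- mesh_from_mask(tube, sp)
  ax <- (20.5 - 1) * 0.25
  cs <- cross_section(mesh, c(20, ax, ax), c(1, 0, 0))
  expect_lt(abs(cs$area / (4 * pi) - 1), 0.03)
  cs60 <- cross_section(mesh, c(20, ax, ax), c(cos(pi / 3), sin(pi / 3), 0))
  expect_lt(abs(cs60$area / (4 * pi / cos(pi / 3)) - 1), 0.03)
})

test_that("the nearest loop is selected when a plane cuts two tubes", {
  sp <- c(0.25, 0.25, 0.25)
  dims <- c(40, 64, 120)
  t1 <- tube_mask(dims, r = 6, z0 = 20.5, y0 = 20.5, x0 = 9, x1 = 111)
  t2 <- tube_mask(dims, r = 6, z0 = 20.5, y0 = 44.5, x0 = 9, x1 = 111)
  mesh <- mesh_from_mask(t1 | t2, sp)
  ax1 <- c(14, (20.5 - 1) * 0.25, (20.5 - 1) * 0.25)
  cs <- cross_section(mesh, ax1, c(1, 0, 0)) # plane crosses both tubes
  expect_lt(cs$centroid_dist, 0.5) # returned loop encloses tube 1 only
  expect_lt(abs(cs$area / (pi * 1.5^2) - 1), 0.05)
})

test_that("csa series flags blobs by the 6 um diameter rule", {
  sp <- c(0.25, 0.25, 0.25)
  dims <- c(48, 48, 140)
  tube <- tube_mask(dims, r = 5.2, z0 = 24.5, y0 = 24.5, x0 = 7, x1 = 133)
  blob <- ball_mask(dims, r = 16, ctr = c(24.5, 24.5, 70)) # 8 um diameter
  mesh <- mesh_from_mask(tube | blob, sp)
  ax <- (24.5 - 1) * 0.25
  skel <- curve3d(cbind(seq(2, 32, length.out = 60), ax, ax))
  ser <- measure_csa_series(mesh, skel, outlier_diameter = 6)
  mid <- abs(unclass(skel)[, 1] - 17.25) < 3.5 # blob region
  expect_true(any(ser$outlier[mid])) # blob-adjacent points flagged
  # every unflagged point passed the diameter rule
  expect_true(all(ser$diameter_um[!ser$outlier] <= 6))
  far <- abs(unclass(skel)[, 1] - 17.25) > 6 &
    unclass(skel)[, 1] > 4 & unclass(skel)[, 1] < 31
  expect_lt(abs(mean(ser$diameter_um[far & !ser$outlier]) / 2.6 - 1), 0.05)
})

test_that("clean constant-radius tubes produce almost no outliers", {
  sp <- c(0.25, 0.25, 0.25)
  tube <- tube_mask(c(48, 48, 140), r = 5.2, z0 = 24.5, y0 = 24.5,
                    x0 = 7, x1 = 133)
  mesh <- mesh_from_mask(tube, sp)
  ax <- (24.5 - 1) * 0.25
  skel <- resample_spline(curve3d(cbind(seq(2.5, 31, length.out = 40), ax, ax)), 3)
  ser <- measure_csa_series(mesh, skel)
  expect_lt(attr(ser, "outlier_fraction"), 0.01)
  expect_lt(sd(ser$csa_um2[!ser$outlier]) / mean(ser$csa_um2[!ser$outlier]),
            0.10)
})

test_that("orientation follows the second-moment principal axis", {
  bar <- matrix(FALSE, 40, 40)
  bar[19:21, 5:35] <- TRUE
  expect_equal(orientation_2d(bar), 0, tolerance = 0.5)
  diag45 <- matrix(FALSE, 60, 60)
  for (i in 5:55) diag45[i + (-1:1), i] <- TRUE
  expect_equal(orientation_2d(diag45), 45, tolerance = 1)
  # rasterized ellipse with major axis at 110 degrees
  img <- matrix(FALSE, 80, 80)
  th <- 110 * pi / 180
  for (r in 1:80) for (c in 1:80) {
    u <- (c - 40) * cos(th) + (r - 40) * sin(th)
    v <- -(c - 40) * sin(th) + (r - 40) * cos(th)
    img[r, c] <- (u / 30)^2 + (v / 8)^2 <= 1
  }
  expect_equal(orientation_2d(img), 110, tolerance = 1)
  expect_error(orientation_2d(ball_mask(c(9, 9, 1), 3, c(5, 5, 1))[, , 1]),
               "isotropic|undefined")
})

# independent oracle: all 2-subset assignments, summed circular resultants
brute_split <- function(a) {
  n <- length(a)
  phi <- 2 * a * pi / 180
  best <- NULL
  for (code in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (sum(grp) < 1 || sum(grp) >= n) next
    R1 <- sqrt(sum(cos(phi[grp]))^2 + sum(sin(phi[grp]))^2)
    R2 <- sqrt(sum(cos(phi[!grp]))^2 + sum(sin(phi[!grp]))^2)
    if (is.null(best) || R1 + R2 > best$score)
      best <- list(score = R1 + R2, grp = grp)
  }
  best
}

test_that("bimodal splitting recovers both orientation families", {
  a <- c(10, 15, 20, 105, 110, 115)
  sp <- split_bimodal(a)
  expect_equal(sp$groups[[1]]["mean"], c(mean = 15), tolerance = 1e-6)
  expect_equal(sp$groups[[2]]["mean"], c(mean = 110), tolerance = 1e-6)
  expect_equal(as.numeric(sp$groups[[1]]["sd"]), 4.08, tolerance = 0.01)
  expect_equal(as.numeric(sp$groups[[2]]["sd"]), 4.08, tolerance = 0.01)
  # matches the exhaustive assignment oracle
  oracle <- brute_split(a)
  expect_true(all(sp$assignment[oracle$grp] == sp$assignment[oracle$grp][1]))
  expect_true(all(sp$assignment[!oracle$grp] == sp$assignment[!oracle$grp][1]))

  # wrap-around: {178, 2, 6} plus a far cluster
  wrap <- c(178, 2, 6, 88, 92, 95)
  spw <- split_bimodal(wrap)
  expect_equal(as.numeric(spw$groups[[1]]["mean"]), 2, tolerance = 1)
  expect_equal(as.numeric(spw$groups[[2]]["mean"]), 91.66, tolerance = 1)

  expect_warning(one <- split_bimodal(rep(42, 6)), "identical")
  expect_length(one$groups, 1)
  expect_error(split_bimodal(c(1, 2, 3)), "at least 4")
})

test_that("two noisy angle families are recovered within 3 degrees", {
  withr::local_seed(123)
  wrap180 <- function(x) x %% 180
  g1 <- wrap180(rnorm(200, 20, 15)) # wraps below 0 into the 160s
  g2 <- wrap180(rnorm(200, 110, 15))
  sp <- split_bimodal(c(g1, g2))
  expect_lt(abs(sp$groups[[1]]["mean"] - 20), 3)
  expect_lt(abs(sp$groups[[2]]["mean"] - 110), 3)
})
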