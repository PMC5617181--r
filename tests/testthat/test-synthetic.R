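test_that("straight phantoms carry their parameters as exact ground truth", {
  spec <- fiber_phantom_spec(kind = "straight", length_um = 12, tilt_deg = 8,
                             orientation_deg = 35, radius_um = 1.0,
                             noise_sd = 0, blur_sigma_um = 0)
  ph <- make_phantom(spec, shape = c(80, 80, 80), spacing = c(0.25, 0.25, 0.25))
  expect_equal(ph$truth$waviness, 1.0, tolerance = 1e-9)
  expect_equal(ph$truth$tilt_deg, 8, tolerance = 1e-6)
  expect_equal(ph$truth$orientation_deg, 35)
  # two-valued image: otsu recovers the ground-truth mask exactly
  mask <- binarize(ph$volume$data, "otsu")
  expect_equal(unclass(mask), ph$mask, ignore_attr = TRUE)
})

test_that("sinusoid amplitude solves the waviness quadrature", {
  lam <- 10
  A <- sinusoid_amplitude_for_waviness(1.37, lam)
  k <- 2 * pi * A / lam
  w <- integrate(function(u) sqrt(1 + k^2 * cos(u)^2), 0, 2 * pi,
                 rel.tol = 1e-10)$value / (2 * pi)
  expect_equal(w, 1.37, tolerance = 1e-6)
  # A = lambda / (2 pi) gives the classic arc ratio ~ 1.2160
  spec <- fiber_phantom_spec(kind = "sinusoidal", length_um = 10,
                             wavelength_um = 10, amplitude_um = 10 / (2 * pi),
                             tilt_deg = 0, orientation_deg = 0)
  ph <- make_phantom(spec, shape = c(72, 72, 72), spacing = c(0.3, 0.3, 0.3))
  oracle <- integrate(function(u) sqrt(1 + cos(u)^2), 0, 2 * pi,
                      rel.tol = 1e-10)$value / (2 * pi)
  expect_equal(ph$truth$waviness, oracle, tolerance = 1e-4)
})

test_that("phantoms are deterministic per seed and truth is resolution-free", {
  spec <- fiber_phantom_spec(kind = "sinusoidal", length_um = 10,
                             wavelength_um = 10, tilt_deg = 4,
                             orientation_deg = 25, seed = 99)
  a <- make_phantom(spec, shape = c(64, 64, 64), spacing = c(0.4, 0.4, 0.4))
  b <- make_phantom(spec, shape = c(64, 64, 64), spacing = c(0.4, 0.4, 0.4))
  expect_identical(a$volume$data, b$volume$data)
  coarse <- make_phantom(spec, shape = c(48, 48, 48),
                         spacing = c(0.55, 0.55, 0.55))
  expect_equal(coarse$truth$waviness, a$truth$waviness, tolerance = 1e-9)
  expect_equal(coarse$truth$tilt_deg, a$truth$tilt_deg, tolerance = 1e-9)
  # the global RNG stream is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(make_phantom(spec, c(48, 48, 48), c(0.55, 0.55, 0.55)))
  expect_identical(rnorm(1), before)
})

test_that("intensity gaps hide signal without touching the truth mask", {
  spec0 <- fiber_phantom_spec(kind = "straight", length_um = 12, tilt_deg = 0,
                              orientation_deg = 0, noise_sd = 0,
                              blur_sigma_um = 0)
  spec1 <- fiber_phantom_spec(kind = "straight", length_um = 12, tilt_deg = 0,
                              orientation_deg = 0, noise_sd = 0,
                              blur_sigma_um = 0, gaps = list(c(4, 8)))
  p0 <- make_phantom(spec0, c(72, 72, 72), c(0.25, 0.25, 0.25))
  p1 <- make_phantom(spec1, c(72, 72, 72), c(0.25, 0.25, 0.25))
  expect_identical(p0$mask, p1$mask)
  expect_gt(sum(p0$volume$data), sum(p1$volume$data))
  # the gap region is at background level in the image
  mid <- p1$volume$data[36, 36, ]
  expect_true(any(mid <= spec1$background + 1e-9 & p1$mask[36, 36, ]))
})

test_that("phantoms refuse to leave the volume", {
  spec <- fiber_phantom_spec(kind = "straight", length_um = 30)
  expect_error(make_phantom(spec, c(64, 64, 64), c(0.25, 0.25, 0.25)),
               "exits the volume")
})

test_that("branching masks label trunk and spurs consistently", {
  trunk <- fiber_phantom_spec(kind = "straight", length_um = 10,
                              tilt_deg = 0, orientation_deg = 0,
                              radius_um = 1.3, noise_sd = 0)
  plain <- make_branching_mask(trunk, list(), shape = c(72, 72, 72),
                               spacing = c(0.25, 0.25, 0.25))
  ph <- make_phantom(trunk, c(72, 72, 72), c(0.25, 0.25, 0.25))
  expect_identical(plain$mask, ph$mask)

  one <- make_branching_mask(
    trunk, list(list(attach_s = 5, direction = c(0, 1, 0),
                     length_um = 3, radius_um = 1.3)),
    shape = c(72, 72, 72), spacing = c(0.25, 0.25, 0.25))
  r <- 1.3
  v_trunk <- pi * r^2 * 10 + 4 / 3 * pi * r^3
  # visible branch: cylinder from the trunk surface outward, plus its end cap
  v_branch <- pi * r^2 * (3 - r) + 2 / 3 * pi * r^3
  ratio <- sum(one$labels == 1) / sum(one$labels > 0)
  expect_lt(abs(ratio - v_trunk / (v_trunk + v_branch)), 0.02)
  expect_error(make_branching_mask(
    trunk, list(list(attach_s = 25, direction = c(0, 1, 0), length_um = 2,
                     radius_um = 1)), c(72, 72, 72), c(0.25, 0.25, 0.25)),
    "not on the trunk")

  two <- make_branching_mask(
    fiber_phantom_spec(kind = "straight", length_um = 16, tilt_deg = 0,
                       orientation_deg = 0, radius_um = 1.3, noise_sd = 0),
    list(list(attach_s = 5, direction = c(0, 1, 0.1), length_um = 5,
              radius_um = 1.1),
         list(attach_s = 11, direction = c(0, -1, -0.1), length_um = 5,
              radius_um = 1.1)),
    shape = c(72, 96, 96), spacing = c(0.25, 0.25, 0.25))
  g <- fast_marching_centerline(two$mask, c(0.25, 0.25, 0.25))
  expect_equal(sum(node_degrees(g) == 3), 2)
})
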