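test_that("binarize separates clean two-valued images exactly", {
  img <- matrix(10, 40, 40)
  disk <- (row(img) - 20)^2 + (col(img) - 20)^2 <= 64
  img[disk] <- 200
  for (meth in c("otsu", "isodata", "max_entropy")) {
    expect_equal(unclass(binarize(img, meth)), disk, ignore_attr = TRUE)
  }
  fixed <- binarize(matrix(c(50, 150, 50, 150), 2), "fixed", level = 100)
  expect_equal(as.vector(fixed), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(binarize(matrix(5, 3, 3), "otsu"), "constant")
  expect_error(binarize(matrix(1:4, 2), "fixed"), "requires a level")
})

test_that("otsu is invariant to adding a constant and handles noisy disks", {
  withr::local_seed(42)
  img <- matrix(10, 64, 64)
  disk <- (row(img) - 32)^2 + (col(img) - 32)^2 <= 21^2
  img[disk] <- 110
  img <- img + rnorm(length(img), 0, 10) # sigma = 10% of contrast
  m1 <- binarize(img, "otsu")
  m2 <- binarize(img + 55.5, "otsu")
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
  dice <- 2 * sum(m1 & disk) / (sum(m1) + sum(disk))
  expect_gte(dice, 0.9)
})

test_that("clean_mask closes small defects and drops small components", {
  expect_equal(sum(clean_mask(array(FALSE, c(4, 4, 4)), 2, 1)), 0)
  img <- matrix(FALSE, 30, 30)
  img[(row(img) - 15)^2 + (col(img) - 15)^2 <= 36] <- TRUE
  noisy <- img
  noisy[2, 2] <- TRUE # isolated pixel
  expect_equal(unclass(clean_mask(noisy, min_component_size = 2)),
               unclass(img), ignore_attr = TRUE)
  # salt noise on a 3D tube: cleanup recovers the noise-free mask
  tube <- tube_mask(c(16, 16, 40), r = 4, z0 = 8.5, y0 = 8.5, x0 = 3, x1 = 38)
  withr::local_seed(7)
  salt <- array(runif(length(tube)) < 0.01, dim(tube)) & !tube
  # keep salt away from the tube so it stays disconnected
  shell <- edt3d(!tube) <= 2
  salt[shell] <- FALSE
  cleaned <- clean_mask(tube | salt, min_component_size = 30)
  expect_equal(cleaned, tube)
})

test_that("region growing respects tolerance, connectivity and the roi", {
  img <- matrix(5, 20, 20)
  expect_equal(sum(region_grow(img, c(10, 10), tolerance = 100)), 400)
  roi <- list(lo = c(5, 5), hi = c(12, 12))
  expect_equal(sum(region_grow(img, c(10, 10), roi, tolerance = 100)), 64)
  expect_error(region_grow(img, c(2, 2), roi, 1), "seed outside")
  img2 <- matrix(0, 10, 10)
  img2[4, 4] <- 9
  expect_equal(sum(region_grow(img2, c(4, 4), tolerance = 0)), 1)
  # two tubes separated by background: growth stays in the seeded tube
  dims <- c(24, 40, 40)
  t1 <- tube_mask(dims, 3, z0 = 12, y0 = 10, x0 = 3, x1 = 38)
  t2 <- tube_mask(dims, 3, z0 = 12, y0 = 28, x0 = 3, x1 = 38) # 4.5 um away
  vol <- array(10, dims) + 90 * (t1 | t2)
  grown <- region_grow(vol, c(12, 10, 20), tolerance = 50)
  expect_true(all(grown[t1]))
  expect_false(any(grown[t2]))
})

test_that("2D skeletons are thin, inside the mask, and chain end-to-end", {
  bar <- matrix(FALSE, 20, 30)
  bar[9:11, 4:27] <- TRUE
  ch <- skeletonize_2d(bar)
  expect_length(ch, 1)
  expect_true(all(ch[[1]][, 1] == 10)) # midline row
  expect_true(all(diff(ch[[1]][, 2]) == 1) || all(diff(ch[[1]][, 2]) == -1))
  sq <- matrix(FALSE, 6, 6)
  sq[3:4, 3:4] <- TRUE
  expect_equal(nrow(skeletonize_2d(sq)[[1]]), 1) # thinning fixed point
  expect_length(skeletonize_2d(matrix(FALSE, 5, 5)), 0)

  # rasterized sine ribbon of width 5: skeleton within 1 px of the curve
  img <- matrix(FALSE, 40, 120)
  xs <- 1:120
  ys <- 20 + 10 * sin(2 * pi * xs / 60)
  for (x in xs) {
    lo <- max(1, round(ys[x]) - 2)
    hi <- min(40, round(ys[x]) + 2)
    img[lo:hi, x] <- TRUE
  }
  ch <- skeletonize_2d(img)
  px <- do.call(rbind, ch)
  d <- abs(px[, 1] - ys[px[, 2]])
  interior <- px[, 2] > 4 & px[, 2] < 116
  expect_lte(mean(d[interior]), 1)
  # skeleton lies within the mask and is one pixel wide (no 2x2 block)
  expect_true(all(img[px]))
  sk <- matrix(FALSE, 40, 120)
  sk[px] <- TRUE
  two_by_two <- sk[-40, -120] & sk[-1, -120] & sk[-40, -1] & sk[-1, -1]
  expect_false(any(two_by_two))
})

test_that("gap filling splines chains into one curve", {
  # single chain: spline residual below 0.2 um
  x <- seq(0, 10, by = 0.2)
  one <- list(cbind(x, sin(x)))
  filled <- fill_gaps_spline(one, max_gap = 1)
  dev <- vapply(seq_len(nrow(filled)), function(i)
    min(sqrt((x - filled[i, 1])^2 + (sin(x) - filled[i, 2])^2)), numeric(1))
  expect_lt(max(dev), 0.2)

  # collinear chains with a 2 um gap: filled curve stays on the line
  a <- cbind(seq(0, 4, 0.25), seq(0, 4, 0.25) * 0.5)
  b <- cbind(seq(6, 10, 0.25), seq(6, 10, 0.25) * 0.5)
  fl <- fill_gaps_spline(list(b, a), max_gap = 3)
  expect_lt(max(abs(fl[, 2] - 0.5 * fl[, 1])), 0.1)
  expect_gte(diff(range(fl[, 1])), 9.9)

  # sine cut into 3 chains with ~1.5 um gaps: RMS within 0.3 um
  xs <- seq(0, 12, by = 0.15)
  ys <- sin(xs)
  keep1 <- xs < 3.5
  keep2 <- xs > 5 & xs < 8.5
  keep3 <- xs > 10
  parts <- list(cbind(xs[keep2], ys[keep2]), cbind(xs[keep1], ys[keep1]),
                cbind(xs[keep3], ys[keep3]))
  fl2 <- fill_gaps_spline(parts, max_gap = 2.5)
  rms <- sqrt(mean(vapply(seq_len(nrow(fl2)), function(i)
    min((xs - fl2[i, 1])^2 + (ys - fl2[i, 2])^2), numeric(1))))
  expect_lt(rms, 0.3)
  # output is at least as long as the longest input chain
  arc <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  expect_gte(arc(fl2), max(vapply(parts, arc, numeric(1))))

  expect_error(fill_gaps_spline(list(a, b), max_gap = 1),
               "exceeds max_gap.*endpoints")
})
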