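#' Amplitude of a sinusoid achieving a target waviness
#'
#' For the planar centerline `y = A sin(2 pi s / lambda)` over whole periods,
#' waviness depends only on `k = 2 pi A / lambda`. Solves for `A` by
#' quadrature + root finding.
#'
#' @param w target waviness (> 1).
#' @param wavelength period, micrometers.
#' @return amplitude `A` in micrometers.
#' @export
sinusoid_amplitude_for_waviness <- function(w, wavelength) {
  if (w <= 1) stop("waviness must exceed 1")
  wav_of_k <- function(k) {
    stats::integrate(function(u) sqrt(1 + k^2 * cos(u)^2), 0, 2 * pi,
                     rel.tol = 1e-10)$value / (2 * pi)
  }
  k <- stats::uniroot(function(k) wav_of_k(k) - w, c(1e-6, 50),
                      tol = 1e-10)$root
  k * wavelength / (2 * pi)
}

#' Specification of a synthetic fiber phantom
#'
#' Defaults mimic second-harmonic-generation collagen acquisitions: fiber
#' radius 1.3 um (mean diameter about 2.6 um), waviness near 1.37, tilt 5
#' degrees, imaged at 0.25 um isotropic sampling with optical blur of one
#' lateral resolution element and moderate detector noise.
#'
#' @param kind centerline generator: `"straight"`, `"sinusoidal"`,
#'   `"helical"` or `"piecewise"`.
#' @param length_um centerline extent along its main axis, micrometers.
#' @param amplitude_um lateral amplitude (sinusoidal/helical); default
#'   chosen so a sinusoid reaches `target_waviness`.
#' @param wavelength_um undulation period, micrometers.
#' @param target_waviness used to derive the default amplitude.
#' @param tilt_deg out-of-plane (latitude) angle of the main axis, degrees.
#' @param orientation_deg in-plane orientation of the main axis, degrees.
#' @param radius_um tube radius: a number or a function of arc position
#'   `s` (micrometers).
#' @param contrast foreground intensity above background.
#' @param background background intensity.
#' @param blur_sigma_um Gaussian optical blur sigma, micrometers.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param gaps list of `c(start_s, end_s)` arc ranges (micrometers) rendered
#'   at background intensity (signal dropouts); ground truth keeps the full
#'   tube.
#' @param control_points for `kind = "piecewise"`: m x 3 matrix of local
#'   centerline control points (micrometers) before tilt/orientation.
#' @param seed RNG seed for the noise, fixed per instance.
#' @return object of class `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(kind = c("sinusoidal", "straight", "helical",
                                        "piecewise"),
                               length_um = 20, amplitude_um = NULL,
                               wavelength_um = 20, target_waviness = 1.37,
                               tilt_deg = 5, orientation_deg = 20,
                               radius_um = 1.3, contrast = 100,
                               background = 10, blur_sigma_um = 0.25,
                               noise_sd = 10, gaps = list(),
                               control_points = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (is.numeric(radius_um) && radius_um <= 0) stop("radius must be positive")
  if (kind %in% c("sinusoidal", "helical")) {
    if (wavelength_um <= 0) stop("wavelength must be positive")
    if (is.null(amplitude_um))
      amplitude_um <- sinusoid_amplitude_for_waviness(target_waviness,
                                                      wavelength_um)
  }
  structure(list(kind = kind, length_um = length_um,
                 amplitude_um = amplitude_um, wavelength_um = wavelength_um,
                 tilt_deg = tilt_deg, orientation_deg = orientation_deg,
                 radius_um = radius_um, contrast = contrast,
                 background = background, blur_sigma_um = blur_sigma_um,
                 noise_sd = noise_sd, gaps = gaps,
                 control_points = control_points, seed = seed),
            class = "fiber_phantom_spec")
}

# local (untilted, unrotated) centerline at arc positions s
phantom_local_curve <- function(spec, s) {
  switch(spec$kind,
    straight = cbind(s, 0 * s, 0 * s),
    # cosine phase: over whole periods the shape is even-symmetric about its
    # midpoint, so its second-moment principal axis is exactly the main axis
    sinusoidal = cbind(s, spec$amplitude_um *
                         cos(2 * pi * s / spec$wavelength_um), 0 * s),
    helical = cbind(s, spec$amplitude_um * cos(2 * pi * s / spec$wavelength_um),
                    spec$amplitude_um * sin(2 * pi * s / spec$wavelength_um)),
    piecewise = {
      cp <- as_matrix3(spec$control_points)
      u <- s / max(s)
      cs <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
      cs <- cs / cs[length(cs)]
      cbind(approx(cs, cp[, 1], xout = u)$y,
            approx(cs, cp[, 2], xout = u)$y,
            approx(cs, cp[, 3], xout = u)$y)
    })
}

phantom_rotation <- function(spec) {
  rotation_about_axis(c(0, 0, 1), spec$orientation_deg) %*%
    rotation_about_axis(c(0, 1, 0), -spec$tilt_deg)
}

radius_at <- function(spec, s) {
  if (is.function(spec$radius_um)) spec$radius_um(s) else
    rep(spec$radius_um, length(s))
}

# paint balls of the given radii around continuous centers into a voxel grid
paint_tube <- function(dims, spacing, centers_um, radii_um) {
  mask <- array(FALSE, dims)
  zc <- centers_um[, 3] / spacing[1]
  yc <- centers_um[, 2] / spacing[2]
  xc <- centers_um[, 1] / spacing[3]
  for (i in seq_len(nrow(centers_um))) {
    r <- radii_um[i]
    z0 <- max(1L, floor(zc[i] - r / spacing[1]) + 1L)
    z1 <- min(dims[1], ceiling(zc[i] + r / spacing[1]) + 1L)
    y0 <- max(1L, floor(yc[i] - r / spacing[2]) + 1L)
    y1 <- min(dims[2], ceiling(yc[i] + r / spacing[2]) + 1L)
    x0 <- max(1L, floor(xc[i] - r / spacing[3]) + 1L)
    x1 <- min(dims[3], ceiling(xc[i] + r / spacing[3]) + 1L)
    if (z0 > z1 || y0 > y1 || x0 > x1) next
    dz <- ((z0:z1) - 1 - zc[i]) * spacing[1]
    dy <- ((y0:y1) - 1 - yc[i]) * spacing[2]
    dx <- ((x0:x1) - 1 - xc[i]) * spacing[3]
    d2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
    sub <- mask[z0:z1, y0:y1, x0:x1, drop = FALSE]
    mask[z0:z1, y0:y1, x0:x1] <- sub | (d2 <= r^2)
  }
  mask
}

#' Render a fiber phantom volume with analytic ground truth
#'
#' Samples the continuous centerline finely, renders the tube as all voxels
#' within the (possibly varying) radius, then produces the intensity image
#' as contrast-on-background with Gaussian blur and seeded additive noise.
#' Ground-truth waviness/tilt/orientation come from the continuous curve by
#' quadrature, independent of the rendering resolution.
#'
#' @param spec a [fiber_phantom_spec()].
#' @param shape volume dimensions `(z, y, x)` in voxels.
#' @param spacing voxel spacing `(z, y, x)`, micrometers.
#' @return list with `volume` (a [image_volume()]), `mask` (ground-truth
#'   tube), and `truth` (list: `centerline` [curve3d()], `waviness`,
#'   `tilt_deg`, `orientation_deg`, `radius_um`).
#' @export
make_phantom <- function(spec, shape = c(128, 128, 128),
                         spacing = c(0.25, 0.25, 0.25)) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  shape <- as.integer(shape)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  step <- min(spacing) / 2
  s <- seq(0, spec$length_um, by = step)
  local <- phantom_local_curve(spec, s)
  Rm <- phantom_rotation(spec)
  pts <- local %*% t(Rm)
  # center the curve in the volume
  ext_um <- c((shape[3] - 1) * spacing[3], (shape[2] - 1) * spacing[2],
              (shape[1] - 1) * spacing[1]) # (x, y, z)
  bb_lo <- apply(pts, 2, min)
  bb_hi <- apply(pts, 2, max)
  shiftv <- ext_um / 2 - (bb_lo + bb_hi) / 2
  pts <- pts + matrix(shiftv, nrow(pts), 3, TRUE)
  r <- radius_at(spec, s)
  margin_lo <- apply(pts, 2, min) - max(r)
  margin_hi <- ext_um - (apply(pts, 2, max) + max(r))
  if (any(margin_lo < max(r)) || any(margin_hi < max(r)))
    stop("fiber exits the volume: enlarge the volume or shrink the fiber ",
         "(margin of 2 x radius required)")
  mask <- paint_tube(shape, spacing, pts, r)
  in_gap <- rep(FALSE, length(s))
  for (g in spec$gaps) in_gap <- in_gap | (s >= g[1] & s <= g[2])
  img_mask <- if (any(in_gap)) {
    paint_tube(shape, spacing, pts[!in_gap, , drop = FALSE], r[!in_gap])
  } else mask
  intens <- spec$background + spec$contrast * img_mask
  if (spec$blur_sigma_um > 0)
    intens <- gaussian_blur3(intens, spec$blur_sigma_um / spacing)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       rnorm(length(intens), 0, spec$noise_sd))
    intens <- intens + array(noise, dim(intens))
  }
  # analytic ground truth from the continuous curve (fixed fine quadrature)
  sq <- seq(0, spec$length_um, length.out = 16385)
  lq <- phantom_local_curve(spec, sq) %*% t(Rm)
  arc <- sum(sqrt(rowSums(diff(lq)^2)))
  chord <- sqrt(sum((lq[nrow(lq), ] - lq[1, ])^2))
  dz <- max(lq[, 3]) - min(lq[, 3])
  dxy <- sqrt(sum((lq[nrow(lq), 1:2] - lq[1, 1:2])^2))
  truth <- list(centerline = curve3d(pts),
                waviness = arc / chord,
                tilt_deg = rad2deg(atan(dz / dxy)),
                orientation_deg = spec$orientation_deg %% 180,
                radius_um = spec$radius_um)
  list(volume = image_volume(intens, spacing), mask = mask, truth = truth)
}

#' Branching phantom mask with trunk/branch labels
#'
#' Renders the trunk tube plus straight side branches attached on the trunk
#' centerline, for exercising skeleton branch trimming.
#'
#' @param trunk_spec a [fiber_phantom_spec()] for the trunk.
#' @param branches list of branch specs: each a list with `attach_s` (arc
#'   position on the trunk, micrometers), `direction` (3-vector, need not be
#'   unit), `length_um`, `radius_um`.
#' @param shape,spacing as in [make_phantom()].
#' @return list with `mask` (union), `labels` (0 background, 1 trunk,
#'   2 branch), and `truth` (trunk centerline and length).
#' @export
make_branching_mask <- function(trunk_spec, branches = list(),
                                shape = c(64, 64, 64),
                                spacing = c(0.25, 0.25, 0.25)) {
  ph <- make_phantom(trunk_spec, shape, spacing)
  trunk_mask <- ph$mask
  labels <- array(0L, dim(trunk_mask))
  labels[trunk_mask] <- 1L
  mask <- trunk_mask
  cl <- unclass(ph$truth$centerline)
  s_cl <- attr(ph$truth$centerline, "arc_length")
  step <- min(spacing) / 2
  for (b in branches) {
    if (b$attach_s < 0 || b$attach_s > max(s_cl))
      stop("branch attach point is not on the trunk")
    at <- cl[which.min(abs(s_cl - b$attach_s)), ]
    dirv <- normalize(as.numeric(b$direction))
    sb <- seq(0, b$length_um, by = step)
    centers <- matrix(at, length(sb), 3, TRUE) + sb %o% dirv
    bm <- paint_tube(dim(trunk_mask), spacing, centers,
                     rep(b$radius_um, length(sb)))
    if (!any(bm & trunk_mask)) stop("branch does not touch the trunk")
    labels[bm & labels == 0L] <- 2L
    mask <- mask | bm
  }
  list(mask = mask, labels = labels,
       truth = list(trunk_centerline = ph$truth$centerline,
                    trunk_length_um = max(s_cl)))
}
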