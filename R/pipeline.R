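#' Pipeline configuration
#'
#' Collects every stage parameter of the fiber reconstruction pipeline with
#' its default. All entries are plain values, so a run's resolved
#' configuration can be serialized beside its outputs.
#'
#' @param input path to the image stack (multi-page TIFF), or `NULL` when a
#'   volume object is passed to [run_pipeline()] directly.
#' @param centerline path to the initial centerline text file, or `NULL`
#'   when a curve object is passed directly.
#' @param spacing voxel spacing `(z, y, x)`, micrometers.
#' @param centerline_units `"um"` or `"voxel"` (see [read_centerline()]).
#' @param plane_halfwidth_um half-width of the cross-sectional sampling
#'   plane, micrometers; the plane spans about 4x the expected fiber
#'   diameter by default.
#' @param sample_spacing_um in-plane sample spacing; default the smallest
#'   voxel spacing component.
#' @param interpolation `"trilinear"` or `"spline"`.
#' @param binarize_method provisional threshold: `"otsu"` (default),
#'   `"isodata"`, `"max_entropy"` or `"fixed"`.
#' @param binarize_level threshold for `"fixed"`.
#' @param threshold_refine `"flux"` (default) refines the provisional
#'   threshold so the mask volume matches the blur-invariant integrated
#'   intensity around the fiber (removing the boundary bias any fixed
#'   histogram threshold inherits from the blur width); `"none"` keeps the
#'   provisional mask.
#' @param presmooth_sigma Gaussian denoising sigma (in samples) applied to
#'   the resliced intensities before thresholding; 0 disables.
#' @param min_component_size,closing_radius mask cleanup (samples).
#' @param spline_factor skeleton resampling factor (3 = three-fold).
#' @param diameter_outlier_um cross-section outlier threshold, micrometers.
#' @param refine_iterations reslice/skeleton refinement passes after the
#'   initial one (0-3).
#' @param end_extension_um length by which the reslicing curve is extended
#'   beyond each end (along the end tangents) so the planes cover the
#'   fiber's end caps, micrometers.
#' @param smooth_sigma_pts skeleton smoothing before tangent estimation.
#' @param fiber_id identifier used in output tables.
#' @param out_dir directory for artifacts (`NULL` = keep in memory only).
#' @param seed seed recorded with the run (the pipeline itself is
#'   deterministic; randomness only enters through phantom generation).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, centerline = NULL,
                            spacing = c(0.25, 0.25, 0.25),
                            centerline_units = "um",
                            plane_halfwidth_um = 6,
                            sample_spacing_um = NULL,
                            interpolation = "trilinear",
                            binarize_method = "otsu",
                            threshold_refine = "flux",
                            binarize_level = NULL,
                            presmooth_sigma = 1,
                            min_component_size = 30,
                            closing_radius = 1,
                            spline_factor = 3,
                            diameter_outlier_um = 6,
                            refine_iterations = 1,
                            end_extension_um = 3,
                            smooth_sigma_pts = 2,
                            fiber_id = "fiber1",
                            out_dir = NULL,
                            seed = 1) {
  if (refine_iterations < 0 || refine_iterations > 3)
    stop("refine_iterations must be between 0 and 3")
  cfg <- list(input = input, centerline = centerline,
              spacing = as.numeric(spacing),
              centerline_units = centerline_units,
              plane_halfwidth_um = plane_halfwidth_um,
              sample_spacing_um = sample_spacing_um,
              interpolation = interpolation,
              binarize_method = binarize_method,
              binarize_level = binarize_level,
              threshold_refine = threshold_refine,
              presmooth_sigma = presmooth_sigma,
              min_component_size = min_component_size,
              closing_radius = closing_radius,
              spline_factor = spline_factor,
              diameter_outlier_um = diameter_outlier_um,
              refine_iterations = refine_iterations,
              end_extension_um = end_extension_um,
              smooth_sigma_pts = smooth_sigma_pts,
              fiber_id = fiber_id, out_dir = out_dir, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()`: a [pipeline_config()];
#'   `write_pipeline_config()`: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

# extend a curve beyond both ends along its end tangents (so reslice planes
# cover the fiber's end caps, which lie beyond the centerline's last point)
extend_curve <- function(curve, ext_um, step_um) {
  if (ext_um <= 0) return(curve)
  p <- unclass(curve)
  n <- nrow(p)
  t1 <- normalize(p[1, ] - p[2, ])
  t2 <- normalize(p[n, ] - p[n - 1, ])
  steps <- seq(step_um, ext_um, by = step_um)
  pre <- p[rep(1, length(steps)), , drop = FALSE] + rev(steps) %o% t1
  post <- p[rep(n, length(steps)), , drop = FALSE] + steps %o% t2
  curve3d(rbind(pre, p, post))
}

# linear resampling of a polyline to a uniform arc-length step
resample_polyline <- function(curve, spacing_um) {
  p <- unclass(curve)
  s <- attr(curve, "arc_length")
  sout <- seq(0, s[length(s)], by = spacing_um)
  if (s[length(s)] - sout[length(sout)] > 1e-6 * spacing_um)
    sout <- c(sout, s[length(s)])
  out <- vapply(1:3, function(j) approx(s, p[, j], xout = sout)$y,
                numeric(length(sout)))
  curve3d(out)
}

# Flux-preserving threshold refinement. Gaussian blur conserves integrated
# intensity, so the fiber's true volume (in samples) is the summed
# background-subtracted intensity over a shell around the provisional mask,
# divided by the plateau contrast; the refined threshold is the level whose
# foreground count matches that volume. This removes the boundary bias that
# any fixed histogram threshold inherits from the blur width.
refine_threshold_flux <- function(sm, valid, prov, spacing3) {
  if (!any(prov)) return(prov)
  shell <- edt3d(!prov, spacing = spacing3) <= 1.0
  shell <- shell & valid
  bg <- median(sm[valid & !shell])
  pk <- as.numeric(quantile(sm[prov], 0.95))
  if (pk - bg < 1e-9) return(prov)
  flux_n <- sum(sm[shell] - bg) / (pk - bg)
  if (!is.finite(flux_n) || flux_n <= 0 || flux_n >= sum(shell)) return(prov)
  L <- as.numeric(quantile(sm[shell], 1 - flux_n / sum(shell)))
  out <- array(FALSE, dim(sm))
  out[shell] <- sm[shell] > L
  attr(out, "threshold") <- L
  out
}

# keep the resliced-mask component that owns the central axis
central_component <- function(mask, grid) {
  lab <- label_components(mask)
  d <- dim(mask)
  ctr <- lab[, grid$R + 1L, grid$C + 1L]
  ctr <- ctr[ctr > 0]
  pick <- if (length(ctr)) {
    as.integer(names(which.max(table(ctr))))
  } else {
    which.max(tabulate(lab[lab > 0]))
  }
  array(lab == pick, d)
}

# largest connected component of a skeleton graph, as a skeleton_graph
largest_component <- function(graph) {
  comps <- igraph::components(graph$graph)
  if (comps$no <= 1) return(graph)
  keep <- which(comps$membership == which.max(comps$csize))
  remap <- match(seq_len(nrow(graph$nodes)), keep)
  e <- graph$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  skeleton_graph(graph$nodes[keep, , drop = FALSE],
                 cbind(remap[e[, 1]], remap[e[, 2]]))
}

#' Run the full fiber reconstruction pipeline
#'
#' Chains reslice, segmentation, back-mapping, fast-marching
#' skeletonization, trunk trimming and spline refinement, iterating the
#' reslice/skeleton stages as configured (the refined skeleton drives the
#' next reslicing), then measures waviness, tilt, orientation and the
#' cross-sectional series on the surface mesh.
#'
#' @param config a [pipeline_config()].
#' @param volume optional [image_volume()] (overrides `config$input`).
#' @param centerline optional [curve3d()] (overrides `config$centerline`).
#' @return list with `summary` (a [measurement_table()]), `series`
#'   (per-point CSA/diameter data.frame), `skeleton` (refined
#'   [curve3d()]), `mesh`, `stack` (last [reslice_volume()] result), `mask`
#'   (original-space binary mask) and the resolved `config`.
#' @export
run_pipeline <- function(config, volume = NULL, centerline = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load"
  fail <- function(e) stop("pipeline stage '", stage, "' failed for ",
                           config$fiber_id, ": ", conditionMessage(e),
                           call. = FALSE)
  tryCatch({
    if (is.null(volume)) volume <- load_stack(config$input, config$spacing)
    if (is.null(centerline)) {
      centerline <- read_centerline(config$centerline, volume,
                                    config$centerline_units)
    }
    sp <- config$sample_spacing_um %||% min(volume$spacing)
    halfn <- max(1L, round(config$plane_halfwidth_um / sp))
    grid <- build_plane_grid(halfn, halfn, sp)
    # slices are placed at half the in-plane spacing so the fanned-out planes
    # of a bending curve still cover every voxel on the outside of bends
    step <- sp / 2
    curve <- resample_polyline(centerline, step)
    stack <- mask3d <- trunk <- NULL
    for (pass in seq_len(config$refine_iterations + 1)) {
      stage <- sprintf("reslice (pass %d)", pass)
      ext <- extend_curve(curve, config$end_extension_um, step)
      frames <- propagate_consistent_frames(ext)
      stack <- reslice_volume(volume, ext, frames, grid,
                              interpolation = config$interpolation)
      stage <- sprintf("segment (pass %d)", pass)
      intens <- stack$intensities
      if (config$presmooth_sigma > 0)
        intens <- gaussian_blur3(intens, rep(config$presmooth_sigma, 3))
      rmask <- binarize(intens, config$binarize_method,
                        config$binarize_level)
      rmask <- rmask & stack$valid
      rmask <- clean_mask(rmask, config$min_component_size,
                          config$closing_radius)
      rmask <- central_component(rmask, grid)
      if (identical(config$threshold_refine, "flux")) {
        rmask <- refine_threshold_flux(intens, stack$valid, rmask,
                                       c(step, sp, sp))
        rmask <- clean_mask(rmask, config$min_component_size,
                            config$closing_radius)
        rmask <- central_component(rmask, grid)
      }
      stage <- sprintf("map back (pass %d)", pass)
      pts <- map_back(mask_to_plane_points(stack, rmask), stack)
      zyx <- round(physical_to_voxel(pts, volume)) + 1
      d <- dim(volume$data)
      ok <- zyx[, 1] >= 1 & zyx[, 1] <= d[1] & zyx[, 2] >= 1 &
        zyx[, 2] <= d[2] & zyx[, 3] >= 1 & zyx[, 3] <= d[3]
      mask3d <- array(FALSE, d)
      mask3d[zyx[ok, , drop = FALSE]] <- TRUE
      mask3d <- clean_mask(mask3d, config$min_component_size, 1)
      stage <- sprintf("skeleton (pass %d)", pass)
      graph <- fast_marching_centerline(mask3d, volume$spacing)
      trunk <- trim_to_trunk(largest_component(graph))
      trunk <- resample_spline(trunk, config$spline_factor)
      curve <- resample_polyline(trunk, step)
    }
    stage <- "mesh"
    mesh <- mesh_from_mask(mask3d, volume$spacing, origin = volume$origin)
    stage <- "measure"
    w <- waviness(trunk)
    tl <- tilt(trunk)
    # in-plane orientation from the skeleton's XY projection: centered on the
    # fiber axis, so boundary/segmentation noise does not bias the moments
    th <- orientation_2d(unclass(trunk)[, 1:2])
    series <- measure_csa_series(mesh, trunk,
                                 outlier_diameter = config$diameter_outlier_um,
                                 smooth_sigma_pts = config$smooth_sigma_pts)
    summary <- measurement_table(
      fiber_id = config$fiber_id,
      parameter = c("waviness", "tilt", "orientation", "mean_csa",
                    "mean_diameter", "csa_outlier_fraction"),
      value = c(w, tl, th, attr(series, "mean_csa"),
                attr(series, "mean_diameter"),
                attr(series, "outlier_fraction")),
      unit = c("dimensionless", "degree", "degree", "um2", "um",
               "dimensionless"),
      outlier = FALSE)
    stage <- "write"
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      pre <- file.path(config$out_dir, config$fiber_id)
      save_stack(round(pmax(stack$intensities, 0)), paste0(pre, "_resliced.tif"))
      save_stack(array(255L * mask3d, dim(mask3d)), paste0(pre, "_mask.tif"))
      utils::write.table(unclass(trunk), paste0(pre, "_skeleton.csv"),
                         sep = ",", row.names = FALSE,
                         col.names = c("x", "y", "z"))
      write_mesh(mesh, paste0(pre, "_mesh.obj"))
      write.csv(cbind(fiber_id = config$fiber_id, series),
                paste0(pre, "_csa_series.csv"), row.names = FALSE)
      write_measurements(summary, paste0(pre, "_summary.csv"))
      write_pipeline_config(config, paste0(pre, "_config.yaml"))
    }
    list(summary = summary, series = series, skeleton = trunk, mesh = mesh,
         stack = stack, mask = mask3d, config = config)
  }, error = fail)
}
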