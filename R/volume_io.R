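#' Image volume container
#'
#' A 3D scalar intensity grid with physical voxel spacing. Arrays are indexed
#' `(z, y, x)`; physical coordinates are reported `(x, y, z)` in micrometers.
#' Voxel centers carry the samples: continuous voxel coordinate `(0,0,0)`
#' (0-based) maps to `origin`.
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param spacing length-3 positive numeric, micrometers per voxel along
#'   `(z, y, x)`.
#' @param origin physical `(x, y, z)` position (micrometers) of voxel
#'   `(0, 0, 0)`.
#' @return an object of class `fiber_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) stop("data must be a 3D array indexed (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (z, y, x) in micrometers")
  origin <- as.numeric(origin)
  if (length(origin) != 3) stop("origin must be a physical (x, y, z) point")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "fiber_volume")
}

#' @export
print.fiber_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fiber_volume> %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.fiber_volume <- function(x) dim(x$data)

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # keep first channel
    p
  })
}

#' Read an image stack from TIFF
#'
#' Accepts a multi-page TIFF or a directory of single-page TIFFs (sorted by
#' file name, taken as z order). Integer pixel data are preserved bit-exact.
#'
#' @param path file or directory path.
#' @param spacing voxel spacing `(z, y, x)` in micrometers.
#' @param origin physical `(x, y, z)` coordinate of the first voxel.
#' @return a [image_volume()].
#' @export
load_stack <- function(path, spacing, origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) stop("directory contains no TIFF files: ", path)
    pages <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else {
    pages <- read_tiff_pages(path)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page dimensions across slices")
  nz <- length(pages)
  a <- array(0, c(nz, dims[1, 1], dims[2, 1]))
  for (i in seq_len(nz)) a[i, , ] <- pages[[i]]
  image_volume(a, spacing, origin)
}

#' Write an image stack as multi-page TIFF
#'
#' Integer-valued volumes are written as 8- or 16-bit (whichever fits);
#' anything else is written as 32-bit float. A load/save/load cycle is
#' voxelwise identical for integer data.
#'
#' @param volume a [image_volume()] or 3D array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(volume, path) {
  a <- if (inherits(volume, "fiber_volume")) volume$data else volume
  mx <- max(a)
  mn <- min(a)
  integerish <- all(a == round(a)) && mn >= 0
  if (integerish && mx <= 255) {
    bits <- 8L; scale <- 255
  } else if (integerish && mx <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    bits <- 32L; scale <- 1
  }
  pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Convert voxel indices to physical coordinates
#'
#' Indices are 0-based `(z, y, x)` voxel coordinates (fractions allowed,
#' extrapolation allowed); physical points are `(x, y, z)` micrometers. The
#' map is `index * spacing + origin` per axis.
#'
#' @param index n x 3 matrix (or length-3 vector) of `(z, y, x)` indices.
#' @param volume a [image_volume()].
#' @return n x 3 matrix of physical `(x, y, z)` points.
#' @export
voxel_to_physical <- function(index, volume) {
  idx <- if (is.null(dim(index))) matrix(index, 1) else as.matrix(index)
  s <- volume$spacing
  o <- volume$origin
  cbind(x = idx[, 3] * s[3] + o[1],
        y = idx[, 2] * s[2] + o[2],
        z = idx[, 1] * s[1] + o[3])
}

#' @rdname voxel_to_physical
#' @param point n x 3 matrix (or length-3 vector) of physical `(x, y, z)`
#'   points.
#' @return for `physical_to_voxel`, an n x 3 matrix of fractional 0-based
#'   `(z, y, x)` indices.
#' @export
physical_to_voxel <- function(point, volume) {
  p <- if (is.null(dim(point))) matrix(point, 1) else as.matrix(point)
  s <- volume$spacing
  o <- volume$origin
  cbind(z = (p[, 3] - o[3]) / s[1],
        y = (p[, 2] - o[2]) / s[2],
        x = (p[, 1] - o[1]) / s[3])
}

#' Per-fiber measurement table
#'
#' Long-format record of fiber measurements; every value carries a unit.
#'
#' @param fiber_id fiber identifier(s).
#' @param parameter parameter name(s), e.g. `"waviness"`.
#' @param value numeric value(s).
#' @param unit unit string(s): `"um"`, `"um2"`, `"degree"` or
#'   `"dimensionless"`.
#' @param outlier logical flag(s).
#' @return data.frame with columns
#'   `fiber_id, parameter, value, unit, outlier`.
#' @export
measurement_table <- function(fiber_id, parameter, value, unit,
                              outlier = FALSE) {
  ok <- unit %in% c("um", "um2", "degree", "dimensionless")
  if (!all(ok)) stop("unknown unit: ", paste(unique(unit[!ok]), collapse = ", "))
  data.frame(fiber_id = fiber_id, parameter = parameter,
             value = as.numeric(value), unit = unit,
             outlier = as.logical(outlier), stringsAsFactors = FALSE)
}

#' Write a measurement table as CSV with a JSON mirror
#'
#' @param table a [measurement_table()] data.frame.
#' @param path output CSV path; a `.json` mirror is written alongside.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(all(c("fiber_id", "parameter", "value", "unit", "outlier") %in%
                  names(table)))
  write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(table, sub("\\.csv$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an initial centerline from text
#'
#' One point per line, `x y z` (whitespace- or comma-separated), in voxel or
#' micrometer units.
#'
#' @param path text/CSV file path.
#' @param volume a [image_volume()]; needed when `units = "voxel"`.
#' @param units `"um"` for physical coordinates, `"voxel"` for 0-based
#'   `(x, y, z)` voxel coordinates converted via the volume spacing.
#' @return a [curve3d()] in physical micrometers.
#' @export
read_centerline <- function(path, volume = NULL, units = c("um", "voxel")) {
  units <- match.arg(units)
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  rows <- lapply(txt, function(l) suppressWarnings(
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]][1:3])))
  keep <- vapply(rows, function(r) length(r) == 3 && all(is.finite(r)), TRUE)
  if (length(rows) && !keep[1]) keep[1] <- NA # tolerate one header line
  if (any(is.na(keep))) { rows <- rows[-1]; keep <- keep[-1] }
  if (!all(keep)) stop("could not parse centerline file: ", path)
  p <- do.call(rbind, rows)
  if (units == "voxel") {
    if (is.null(volume)) stop("voxel units require the volume")
    p <- voxel_to_physical(p[, c(3, 2, 1), drop = FALSE], volume)
  }
  curve3d(p)
}
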