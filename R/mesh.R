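#' Triangular surface mesh
#'
#' @param vertices n x 3 matrix of `(x, y, z)` points, micrometers.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as_matrix3(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("faces index nonexistent vertices")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.3f um^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' @rdname surface_mesh
#' @param mesh a `surface_mesh`.
#' @return `mesh_area()`: total triangle area (um^2); `mesh_volume()`:
#'   enclosed volume (um^3) by the divergence theorem (watertight meshes).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname surface_mesh
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  abs(sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
            p1[, 2] * (p2[, 1] * p3[, 3] - p3[, 1] * p2[, 3]) +
            p1[, 3] * (p2[, 1] * p3[, 2] - p3[, 1] * p2[, 2]))) / 6
}

# connected face components via shared vertices
mesh_face_components <- function(mesh) {
  nf <- nrow(mesh$faces)
  vert_of <- split(rep(seq_len(nf), 3), as.vector(mesh$faces))
  # union-find over faces
  parent <- seq_len(nf)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (fl in vert_of) {
    if (length(fl) > 1) {
      r <- find(fl[1])
      for (j in fl[-1]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  roots <- vapply(seq_len(nf), find, 1L)
  match(roots, unique(roots))
}

#' Isosurface mesh of a binary fiber mask
#'
#' Gaussian-presmooths the 0/1 mask, extracts the level-0.5 isosurface on
#' the consistent tetrahedral decomposition of the voxel lattice (watertight
#' by construction), applies Laplacian smoothing with a volume-preserving
#' rescale, and drops components below a face-count floor.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param spacing voxel spacing `(z, y, x)` micrometers.
#' @param smoothing_iters Laplacian smoothing iterations (0 = none).
#' @param presmooth_sigma_vox Gaussian presmoothing sigma in voxels.
#' @param min_component_faces components with fewer faces are deleted.
#' @param origin physical `(x, y, z)` of voxel `(0,0,0)`.
#' @return a [surface_mesh()] in physical micrometers.
#' @export
mesh_from_mask <- function(mask, spacing = c(1, 1, 1), smoothing_iters = 15,
                           presmooth_sigma_vox = 1, min_component_faces = 50,
                           origin = c(0, 0, 0)) {
  if (!any(mask)) stop("empty mask: nothing to mesh")
  spacing <- rep(spacing, length.out = 3)
  field <- array(as.numeric(mask), dim(mask))
  # pad so surfaces close at the volume border
  d <- dim(field)
  fp <- array(0, d + 2)
  fp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  if (presmooth_sigma_vox > 0)
    fp <- gaussian_blur3(fp, rep(presmooth_sigma_vox, 3))
  res <- .march_tets_cpp(as.numeric(fp), dim(fp), spacing, 0.5)
  v <- res$vertices
  # unpad and shift to the requested origin
  v[, 1] <- v[, 1] - spacing[3] + origin[1]
  v[, 2] <- v[, 2] - spacing[2] + origin[2]
  v[, 3] <- v[, 3] - spacing[1] + origin[3]
  mesh <- surface_mesh(v, res$faces)
  if (min_component_faces > 0 && nrow(mesh$faces)) {
    compid <- mesh_face_components(mesh)
    keep <- which(tabulate(compid) >= min_component_faces)
    if (!length(keep)) keep <- which.max(tabulate(compid))
    fkeep <- mesh$faces[compid %in% keep, , drop = FALSE]
    used <- sort(unique(as.vector(fkeep)))
    remap <- match(fkeep, used)
    mesh <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                         matrix(remap, ncol = 3))
  }
  if (smoothing_iters > 0) mesh <- smooth_mesh(mesh, smoothing_iters)
  mesh
}

#' Laplacian mesh smoothing with volume preservation
#'
#' Each iteration moves every vertex halfway to the mean of its neighbors,
#' then rescales the mesh about its centroid to restore the enclosed volume
#' (countering Laplacian shrinkage).
#'
#' @param mesh a [surface_mesh()].
#' @param iterations smoothing iterations.
#' @return smoothed [surface_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 5) {
  if (iterations <= 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  src <- c(e[, 1], e[, 2])
  dst <- c(e[, 2], e[, 1])
  nn <- tabulate(src, nbins = nrow(v))
  v0_vol <- mesh_volume(mesh)
  for (it in seq_len(iterations)) {
    agg <- rowsum(v[dst, , drop = FALSE], src)
    present <- as.integer(rownames(agg))
    mean_nb <- v
    mean_nb[present, ] <- agg / nn[present]
    v <- v + 0.5 * (mean_nb - v)
    m2 <- surface_mesh(v, f)
    vol <- mesh_volume(m2)
    if (vol > 0 && v0_vol > 0) {
      ctr <- colMeans(v)
      v <- sweep(sweep(v, 2, ctr), 1, (v0_vol / vol)^(1 / 3), "*")
      v <- sweep(v, 2, ctr, "+")
    }
  }
  surface_mesh(v, f)
}

#' Export a mesh as OBJ or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; format from the extension (`.obj` or `.ply`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  } else {
    stop("unsupported mesh format: ", path)
  }
  invisible(path)
}
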