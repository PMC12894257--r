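#' Voxel grid for brain maps
#'
#' A `volume_grid` holds the voxel lattice every map in the pipeline lives
#' on: dimensions, a 4x4 voxel-to-world (MNI mm, RAS+) affine, and a logical
#' gray-matter analysis mask. Voxel indices are 0-based in the affine
#' convention; all world coordinates are in mm.
#'
#' @param voxel_size voxel edge length(s) in mm; scalar or length-3.
#' @param bbox 2x3 matrix of world-coordinate bounds (min row, max row) in mm.
#'   Defaults to the MNI bounding box x -90..90, y -126..90, z -72..108.
#' @param mask optional logical array with one entry per voxel; defaults to
#'   all-true until [set_mask()] or [ellipsoid_mask()] installs one.
#' @return an object of class `volume_grid` with fields `dims`, `voxel_size`,
#'   `affine` (4x4), and `mask`.
#' @export
make_grid <- function(voxel_size = 2,
                      bbox = rbind(c(-90, -126, -72), c(90, 90, 108)),
                      mask = NULL) {
  vs <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(vs > 0), nrow(bbox) == 2L, ncol(bbox) == 3L)
  dims <- as.integer(floor((bbox[2L, ] - bbox[1L, ]) / vs)) + 1L
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(vs)
  affine[1:3, 4] <- bbox[1L, ]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  g <- structure(
    list(dims = dims, voxel_size = vs, affine = affine, mask = mask),
    class = "volume_grid"
  )
  validate_grid(g)
}

validate_grid <- function(g) {
  stopifnot(inherits(g, "volume_grid"))
  if (abs(det(g$affine)) < .Machine$double.eps) {
    stop("grid affine must be invertible")
  }
  if (!any(g$mask)) stop("grid mask must contain at least one voxel")
  if (!identical(dim(g$mask), as.integer(g$dims))) {
    stop("mask dimensions do not match grid dims")
  }
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels @ %s mm, %d in mask\n",
    x$dims[1], x$dims[2], x$dims[3],
    paste(x$voxel_size, collapse = "x"), sum(x$mask)
  ))
  invisible(x)
}

#' Replace the analysis mask of a grid
#' @param grid a `volume_grid`.
#' @param mask logical array matching the grid dims.
#' @export
set_mask <- function(grid, mask) {
  grid$mask <- array(as.logical(mask), dim = grid$dims)
  validate_grid(grid)
}

#' Ellipsoidal brain-like mask
#'
#' Builds a smooth closed analysis domain used by the synthetic pipeline in
#' place of a tissue-derived gray-matter mask.
#'
#' @param grid a `volume_grid`.
#' @param center ellipsoid center, MNI mm.
#' @param radii semi-axes in mm.
#' @export
ellipsoid_mask <- function(grid, center = c(0, -18, 8),
                           radii = c(70, 85, 65)) {
  xyz <- voxel_centers(grid)
  u <- sweep(xyz, 2L, center)
  inside <- (u[, 1] / radii[1])^2 + (u[, 2] / radii[2])^2 +
    (u[, 3] / radii[3])^2 <= 1
  set_mask(grid, array(inside, dim = grid$dims))
}

#' World coordinates of every voxel center
#' @param grid a `volume_grid`.
#' @return an n-voxel x 3 matrix in array (column-major) order.
#' @export
voxel_centers <- function(grid) {
  ijk <- arrayInd(seq_len(prod(grid$dims)), grid$dims) - 1L
  voxel_to_world(grid, ijk)
}

#' Convert 0-based voxel indices to world mm
#' @param grid a `volume_grid`.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(grid$affine[1:3, 1:3] %*% t(ijk) + grid$affine[1:3, 4L])
}

#' Convert world mm to fractional 0-based voxel indices
#' @param grid a `volume_grid`.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4L])
}

#' Nearest-voxel linear index for world coordinates
#'
#' A point belongs to the voxel whose center is nearest; points mapping
#' outside the lattice get NA.
#' @param grid a `volume_grid`.
#' @param xyz n x 3 world coordinates (mm).
#' @return integer vector of 1-based linear array indices (NA outside grid).
#' @export
nearest_voxel <- function(grid, xyz) {
  ijk <- round(world_to_voxel(grid, xyz))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid$dims[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$dims[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$dims[3]
  idx <- rep(NA_integer_, nrow(ijk))
  idx[ok] <- 1L + ijk[ok, 1] + grid$dims[1] * (ijk[ok, 2] +
    grid$dims[2] * ijk[ok, 3])
  idx
}

#' Statistical brain map on a grid
#'
#' @param grid a `volume_grid`.
#' @param values numeric: either one value per voxel (full array order) or
#'   one per in-mask voxel.
#' @param kind one of "t", "z", "d", "p".
#' @return a `stat_map` with a full-length `values` vector (NA outside mask).
#' @export
stat_map <- function(grid, values, kind = c("t", "z", "d", "p")) {
  kind <- match.arg(kind)
  nvox <- prod(grid$dims)
  nmask <- sum(grid$mask)
  full <- rep(NA_real_, nvox)
  if (length(values) == nvox) {
    full[grid$mask] <- values[grid$mask]
  } else if (length(values) == nmask) {
    full[grid$mask] <- values
  } else {
    stop("values length matches neither the grid nor its mask")
  }
  if (any(!is.finite(full[grid$mask]))) {
    stop("stat_map values must be finite inside the mask")
  }
  structure(list(grid = grid, values = full, kind = kind),
            class = "stat_map")
}

#' In-mask values of a stat map
#' @param map a `stat_map`.
#' @export
mask_values <- function(map) map$values[map$grid$mask]

#' @export
print.stat_map <- function(x, ...) {
  v <- mask_values(x)
  cat(sprintf("<stat_map kind=%s> %d in-mask voxels, range [%.3g, %.3g]\n",
              x$kind, length(v), min(v), max(v)))
  invisible(x)
}

#' Write a stat map as NIfTI-1
#'
#' Out-of-mask voxels are written as 0; the mask itself can be written as a
#' uint8 companion with [write_mask()].
#' @param map a `stat_map`.
#' @param path output .nii or .nii.gz path.
#' @export
write_stat_map <- function(map, path) {
  arr <- array(ifelse(is.na(map$values), 0, map$values), dim = map$grid$dims)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(map$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map onto a grid
#' @param path NIfTI file.
#' @param grid expected `volume_grid`; dims must match.
#' @param kind statistic kind of the stored values.
#' @export
read_stat_map <- function(path, grid, kind = "t") {
  img <- RNifti::readNifti(path)
  if (!identical(as.integer(dim(img)[1:3]), as.integer(grid$dims))) {
    stop(sprintf("map dimensions %s do not match grid %s",
                 paste(dim(img), collapse = "x"),
                 paste(grid$dims, collapse = "x")))
  }
  stat_map(grid, as.numeric(img), kind = kind)
}

#' Write / read the grid mask as a 0/1 NIfTI volume
#' @param grid a `volume_grid`.
#' @param path NIfTI path.
#' @export
write_mask <- function(grid, path) {
  img <- RNifti::asNifti(array(as.integer(grid$mask), dim = grid$dims),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, grid) {
  img <- RNifti::readNifti(path)
  if (!identical(as.integer(dim(img)[1:3]), as.integer(grid$dims))) {
    stop("mask dimensions do not match grid")
  }
  set_mask(grid, array(as.numeric(img) != 0, dim = grid$dims))
}
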