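#' Volume grid geometry
#'
#' A `volume_grid` describes the shared sampling geometry of a cohort:
#' the number of voxels per axis, the voxel size in mm, and a 4x4 affine
#' mapping zero-based voxel indices to world (mm) coordinates. The world
#' frame follows the template convention: x increases to the right,
#' y to anterior, z to superior, so the left hemisphere sits at negative x.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0). Defaults to 1 mm isotropic.
#' @param affine 4x4 numeric matrix mapping zero-based voxel indices
#'   `(i, j, k, 1)` to world mm. If `NULL`, a centered axis-aligned affine is
#'   built so the grid straddles the origin symmetrically (mid-sagittal plane
#'   at x = 0).
#' @return An object of class `volume_grid` with fields `dims`, `voxel_size`,
#'   `affine`.
#' @examples
#' g <- volume_grid(c(40, 48, 40), c(4, 4, 4))
#' voxel_to_world(g, c(1, 1, 1))
#' @export
volume_grid <- function(dims, voxel_size = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(dims) == 3L, length(voxel_size) == 3L)
  if (any(dims < 1L)) stop("all grid dimensions must be >= 1")
  if (any(voxel_size <= 0)) stop("all voxel sizes must be > 0")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dims - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine))) {
    stop("affine must be a finite 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    stop("affine must be invertible")
  }
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Compare two grids for equality
#'
#' @param a,b `volume_grid` objects.
#' @param tol absolute tolerance on voxel size and affine entries.
#' @return `TRUE` if dims match and geometry agrees within `tol`.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$dims, b$dims) &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b)) {
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(a$dims, collapse = "x"), paste(b$dims, collapse = "x")))
  }
  invisible(TRUE)
}

#' Convert voxel indices to world coordinates
#'
#' Indices are 1-based (R convention); the affine is applied to the
#' zero-based index as in the NIfTI standard.
#'
#' @param grid a `volume_grid`.
#' @param ijk integer vector of length 3 or an n x 3 matrix of 1-based voxel
#'   indices.
#' @return numeric vector of length 3 or n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  single <- is.null(dim(ijk))
  ijk <- rbind(ijk)
  h <- cbind(ijk - 1, 1)
  w <- h %*% t(grid$affine)
  w <- w[, 1:3, drop = FALSE]
  if (single) drop(w) else w
}

#' Extract a grid from a NIfTI image
#' @param image an object readable by [RNifti::niftiHeader()].
#' @return a `volume_grid`.
#' @keywords internal
grid_from_nifti <- function(image) {
  dims <- dim(image)[1:3]
  aff <- unclass(RNifti::xform(image))
  attributes(aff) <- list(dim = c(4L, 4L))
  vs <- abs(RNifti::pixdim(image))[1:3]
  volume_grid(dims, vs, aff)
}

#' Write a 3-D array as a NIfTI volume
#'
#' @param data 3-D numeric or integer array matching `grid$dims`.
#' @param grid a `volume_grid` supplying the affine and voxel size.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  stopifnot(all(dim(data)[1:3] == grid$dims))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$voxel_size
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
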