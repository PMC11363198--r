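#' Volumetric images and binary masks
#'
#' A `volume_image` holds a 3-D numeric array plus a voxel-index-to-world
#' affine (0-based voxel indices, RAS millimetres). A `binary_mask` is a
#' `volume_image` whose values are restricted to exactly 0 or 1.
#'
#' @param values 3-D numeric array.
#' @param affine Voxel-to-world [affine_matrix()] (0-based indices to RAS mm).
#' @return A `volume_image` (or `binary_mask`) list with elements `values`
#'   and `affine`.
#' @export
volume_image <- function(values, affine = diag(4)) {
  if (length(dim(values)) != 3L) {
    abort_validation("a volume must be a 3-D array")
  }
  storage.mode(values) <- "double"
  affine <- affine_matrix(affine)
  edges <- sqrt(colSums(unclass(affine)[1:3, 1:3]^2))
  if (any(edges <= 0)) abort_validation("voxel edge lengths must be positive")
  structure(list(values = values, affine = affine),
            class = "fsub_volume")
}

#' @rdname volume_image
#' @export
binary_mask <- function(values, affine = diag(4)) {
  v <- volume_image(values, affine)
  if (!all(v$values %in% c(0, 1))) {
    abort_validation("a binary mask may contain only 0 and 1")
  }
  class(v) <- c("fsub_mask", class(v))
  v
}

#' @export
print.fsub_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, %.3g mm3/voxel, %d nonzero\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              voxel_volume_mm3(x), sum(x$values != 0)))
  invisible(x)
}

#' Voxel geometry helpers
#'
#' `voxel_volume_mm3()` is the parallelepiped volume of one voxel;
#' `mask_volume_mm3()` multiplies it by the number of set voxels;
#' `voxel_centers_mm()` returns the world coordinates of given (or all
#' nonzero) 0-based voxel indices.
#'
#' @param vol A [volume_image()] or [binary_mask()].
#' @return A scalar volume in cubic millimetres, or an n x 3 matrix.
#' @export
voxel_volume_mm3 <- function(vol) {
  abs(det(unclass(vol$affine)[1:3, 1:3]))
}

#' @rdname voxel_volume_mm3
#' @export
mask_volume_mm3 <- function(vol) {
  sum(vol$values != 0) * voxel_volume_mm3(vol)
}

#' @rdname voxel_volume_mm3
#' @param ijk Optional n x 3 matrix of 0-based voxel indices; defaults to all
#'   nonzero voxels in `vol`.
#' @export
voxel_centers_mm <- function(vol, ijk = NULL) {
  if (is.null(ijk)) ijk <- nonzero_voxels(vol)
  affine_apply_points(vol$affine, ijk)
}

# 0-based (i, j, k) indices of nonzero voxels, in lexicographic (i, j, k)
# order so downstream tie-breaking is deterministic.
nonzero_voxels <- function(vol) {
  idx <- which(vol$values != 0)
  if (length(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  ijk <- arrayInd(idx, dim(vol$values)) - 1L
  ijk <- ijk[order(ijk[, 1], ijk[, 2], ijk[, 3]), , drop = FALSE]
  storage.mode(ijk) <- "double"
  ijk
}

# World mm -> fractional 0-based voxel coordinates.
world_to_voxel <- function(vol, pts) {
  affine_apply_points(affine_inverse(vol$affine), pts)
}

# TRUE where the rounded voxel index of each point is inside the grid and set.
points_in_mask <- function(mask, pts) {
  vox <- round(world_to_voxel(mask, pts))
  dm <- dim(mask$values)
  ok <- vox[, 1] >= 0 & vox[, 1] < dm[1] &
        vox[, 2] >= 0 & vox[, 2] < dm[2] &
        vox[, 3] >= 0 & vox[, 3] < dm[3]
  hit <- logical(nrow(vox))
  if (any(ok)) {
    lin <- vox[ok, 1] + dm[1] * (vox[ok, 2] + dm[2] * vox[ok, 3]) + 1
    hit[ok] <- mask$values[lin] != 0
  }
  hit
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(unclass(a$affine) - unclass(b$affine))) <= tol
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti. `read_volume()` returns a 3-D
#' [volume_image()]; the affine is taken from the sform when set, else the
#' qform. 4-D inputs are rejected (use [read_5tt()] for tissue
#' segmentations). `write_volume()` writes an uncompressed or gzipped
#' NIfTI-1 file depending on the extension.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a [volume_image()].
#' @export
read_volume <- function(path) {
  stopifnot_file_exists(path, "NIfTI file")
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4] == 1L) {
    im <- array(as.double(im), dim = d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    abort_validation(sprintf("expected a 3-D volume, got %d-D: %s",
                             length(d), path))
  }
  aff <- nifti_affine(im)
  volume_image(array(as.double(im), dim = d), aff)
}

#' @rdname read_volume
#' @param vol A [volume_image()] or [binary_mask()].
#' @export
write_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$values)
  aff <- unclass(vol$affine)
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::qform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

nifti_affine <- function(im) {
  aff <- RNifti::xform(im, useQuaternionFirst = FALSE)
  affine_matrix(matrix(as.double(aff), 4, 4))
}
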