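#' Five-tissue-type segmentations
#'
#' Holds the five partial-volume maps of the MRtrix-style 5tt convention —
#' cortical gray matter, subcortical gray matter, white matter, CSF, and
#' pathological tissue — on one grid. Per-voxel sums may exceed 1 slightly
#' from resampling; more than 5% is rejected.
#'
#' @param maps List of five 3-D arrays in the order above, values in `[0, 1]`.
#' @param affine Voxel-to-world [affine_matrix()].
#' @return An `fsub_5tt` list with `maps` (named) and `affine`.
#' @export
tissue_segmentation <- function(maps, affine = diag(4)) {
  if (length(maps) != 5L) abort_validation("a 5tt segmentation needs exactly 5 maps")
  names(maps) <- c("gm_cortical", "gm_subcortical", "wm", "csf", "pathological")
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort_validation("all five tissue maps must share one shape")
  }
  maps <- lapply(maps, function(m) {
    storage.mode(m) <- "double"
    if (min(m) < 0 || max(m) > 1) {
      abort_validation("partial volumes must lie in [0, 1]")
    }
    m
  })
  total <- Reduce(`+`, maps)
  if (max(total) > 1.05) {
    abort_validation("per-voxel tissue fractions sum to more than 1.05")
  }
  structure(list(maps = maps, affine = affine_matrix(affine)),
            class = "fsub_5tt")
}

#' Read a 4-D 5tt NIfTI image
#'
#' Expects five volumes in the MRtrix 5tt order (cortical GM, subcortical
#' GM, WM, CSF, pathological).
#'
#' @param path NIfTI path.
#' @return A [tissue_segmentation()].
#' @export
read_5tt <- function(path) {
  stopifnot_file_exists(path, "5tt NIfTI file")
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L || d[4] != 5L) {
    abort_validation(sprintf("a 5tt image must be 4-D with 5 volumes, got %s",
                             paste(d, collapse = "x")))
  }
  arr <- array(as.double(im), dim = d)
  maps <- lapply(1:5, function(k) arr[, , , k])
  tissue_segmentation(maps, nifti_affine(im))
}

#' Write a 4-D 5tt NIfTI image
#' @param seg A [tissue_segmentation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_5tt <- function(seg, path) {
  d <- dim(seg$maps[[1]])
  arr <- array(0, dim = c(d, 5L))
  for (k in 1:5) arr[, , , k] <- seg$maps[[k]]
  im <- RNifti::asNifti(arr)
  aff <- unclass(seg$affine)
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::qform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Probabilistic gray/white-matter interface from a 5tt segmentation
#'
#' Scores each voxel by `min(1, 4 * g * w)` where `w` is the white-matter
#' partial volume and `g` the cortical gray-matter partial volume (plus
#' subcortical GM when `include_subcortical`). The product form peaks at
#' exactly 1 for a 50/50 mix and vanishes in pure tissue, which is what an
#' interface map should do; it is a deliberate native definition of the
#' interface score, documented here rather than inherited from any external
#' tool.
#'
#' @param seg A [tissue_segmentation()].
#' @param include_subcortical Add subcortical GM into the gray fraction
#'   (default `FALSE`: cortical fROIs are the use case).
#' @return A [volume_image()] with values in `[0, 1]`.
#' @export
compute_gmwmi <- function(seg, include_subcortical = FALSE) {
  g <- seg$maps$gm_cortical
  if (include_subcortical) g <- g + seg$maps$gm_subcortical
  w <- seg$maps$wm
  if (all(g == 0) && all(w == 0)) {
    abort_validation("segmentation is all zero; cannot compute an interface")
  }
  score <- pmin(1, 4 * g * w)
  volume_image(array(score, dim = dim(w)), seg$affine)
}

#' Binarize a probability image
#'
#' Strict threshold: voxels with probability strictly greater than
#' `threshold` are set.
#'
#' @param prob A [volume_image()] with values in `[0, 1]`.
#' @param threshold Scalar in `[0, 1)`; default 0.25 keeps a contiguous
#'   interface sheet while excluding trace partial-volume mixing.
#' @return A [binary_mask()].
#' @export
binarize <- function(prob, threshold = 0.25) {
  if (!is_scalar_number(threshold) || threshold < 0 || threshold >= 1) {
    abort_parameter("threshold must lie in [0, 1)")
  }
  if (min(prob$values) < 0 || max(prob$values) > 1) {
    abort_validation("binarize expects probabilities in [0, 1]")
  }
  m <- (prob$values > threshold) * 1
  if (!any(m == 1)) fsub_warn("binarization produced an empty mask")
  binary_mask(array(m, dim = dim(prob$values)), prob$affine)
}

#' Intersect two binary masks
#'
#' Voxelwise product of two masks on an identical grid (shape equal, affines
#' within 1e-4 mm). There is no silent resampling: a grid mismatch is an
#' error, because resampling here would hide registration errors between the
#' functional and diffusion spaces.
#'
#' @param a,b [binary_mask()] objects on one grid.
#' @return A [binary_mask()]; empty intersections warn.
#' @export
intersect_masks <- function(a, b) {
  if (!same_grid(a, b)) {
    abort_space("masks are not on the same grid (shape/affine mismatch); resample explicitly before intersecting")
  }
  m <- a$values * b$values
  if (!any(m == 1)) fsub_warn("mask intersection is empty")
  binary_mask(m, a$affine)
}
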