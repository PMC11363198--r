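#' 4x4 affine transforms
#'
#' An `fsub_affine` is a plain 4x4 numeric matrix mapping homogeneous source
#' coordinates (voxel indices or millimetres) to target millimetre
#' coordinates. The last row must be (0, 0, 0, 1) and the upper-left 3x3
#' block must be invertible.
#'
#' @param m A 4x4 numeric matrix.
#' @return A validated 4x4 matrix of class `fsub_affine`.
#' @export
affine_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (!identical(dim(m), c(4L, 4L))) {
    abort_validation("an affine must be a 4x4 matrix")
  }
  if (any(!is.finite(m))) abort_validation("affine entries must be finite")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8) {
    abort_validation("the last row of an affine must be (0, 0, 0, 1)")
  }
  d <- det(m[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) {
    abort_validation("the upper-left 3x3 block of an affine must be invertible")
  }
  structure(m, class = c("fsub_affine", "matrix", "array"))
}

#' Read a 4x4 affine from a text file
#'
#' Accepts two dialects: a plain whitespace-delimited 4x4 matrix (possibly
#' with `#`-prefixed comment lines), and the ITK text-transform layout whose
#' `Parameters:` line carries 9 matrix entries followed by a 3-vector
#' translation (with `FixedParameters:` ignored). Typical use is the rigid
#' registration taking FreeSurfer surface space into ACPC-aligned DWI space.
#'
#' @param path Path to the text file.
#' @return An [affine_matrix()].
#' @export
read_affine_text <- function(path) {
  stopifnot_file_exists(path, "affine file")
  lines <- readLines(path, warn = FALSE)
  itk_par <- grep("^\\s*Parameters\\s*:", lines, value = TRUE)
  if (length(itk_par) == 1L) {
    vals <- scan(text = sub("^\\s*Parameters\\s*:", "", itk_par),
                 what = double(), quiet = TRUE)
    if (length(vals) != 12L) {
      abort_format("ITK-style affine must carry 12 parameters (9 matrix + 3 offset)")
    }
    m <- diag(4)
    m[1:3, 1:3] <- matrix(vals[1:9], nrow = 3, byrow = TRUE)
    m[1:3, 4] <- vals[10:12]
    return(affine_matrix(m))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  vals <- scan(text = paste(lines, collapse = " "), what = double(), quiet = TRUE)
  if (length(vals) == 12L) vals <- c(vals, 0, 0, 0, 1)
  if (length(vals) != 16L) {
    abort_format(sprintf(
      "affine text must contain 16 (or 12) numbers; found %d in %s",
      length(vals), path))
  }
  affine_matrix(matrix(vals, nrow = 4, byrow = TRUE))
}

#' Write a 4x4 affine as plain text
#'
#' @param affine An [affine_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_affine_text <- function(affine, path) {
  affine <- affine_matrix(affine)
  writeLines(apply(unclass(affine), 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  }), path)
  invisible(path)
}

#' Invert an affine
#' @param affine An [affine_matrix()].
#' @return The inverse affine.
#' @export
affine_inverse <- function(affine) {
  affine_matrix(solve(unclass(affine_matrix(affine))))
}

#' Apply an affine transform
#'
#' Maps every coordinate of `x` through `affine` homogeneously. Methods exist
#' for bare n x 3 point matrices, [tractogram()] objects, [surface_mesh()]
#' objects (whose cached normals, if any, are dropped so they are recomputed
#' on the transformed geometry rather than sheared), and numeric 3-vectors.
#'
#' @param x Points, mesh, or tractogram.
#' @param affine An [affine_matrix()].
#' @return An object of the same type as `x` with transformed coordinates.
#' @export
apply_affine <- function(x, affine) {
  affine <- affine_matrix(affine)
  UseMethod("apply_affine")
}

#' @export
apply_affine.default <- function(x, affine) {
  affine <- affine_matrix(affine)
  affine_apply_points(affine, x)
}

#' @export
apply_affine.fsub_tractogram <- function(x, affine) {
  affine <- affine_matrix(affine)
  x$streamlines <- lapply(x$streamlines, function(s) affine_apply_points(affine, s))
  x
}

#' @export
apply_affine.fsub_surface <- function(x, affine) {
  affine <- affine_matrix(affine)
  x <- surface_to_world(x)
  x$vertices <- affine_apply_points(affine, x$vertices)
  x$normals <- NULL
  x
}
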