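# Typed condition helpers. All package errors inherit "fsub_error" plus a
# subclass naming the failure mode, so callers (and the CLI) can map error
# classes to exit codes without string matching.

fsub_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "fsub_error"), ...)
}

abort_format    <- function(msg, ...) fsub_abort(msg, "fsub_format_error", ...)
abort_dialect   <- function(msg, ...) fsub_abort(msg, "fsub_dialect_error", ...)
abort_corrupt   <- function(msg, ...) fsub_abort(msg, "fsub_corrupt_error", ...)
abort_space     <- function(msg, ...) fsub_abort(msg, "fsub_space_error", ...)
abort_parameter <- function(msg, ...) fsub_abort(msg, "fsub_parameter_error", ...)
abort_validation <- function(msg, ...) fsub_abort(msg, "fsub_validation_error", ...)
abort_io        <- function(msg, ...) fsub_abort(msg, "fsub_io_error", ...)

fsub_warn <- function(message, class = "fsub_warning") {
  rlang::warn(message, class = class)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @keywords internal
stopifnot_file_exists <- function(path, what = "file") {
  if (!file.exists(path)) {
    abort_io(sprintf("%s not found: %s", what, path))
  }
  invisible(path)
}

# Euclidean norms of the rows of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Homogeneous application of a 4x4 affine to an n x 3 coordinate matrix.
affine_apply_points <- function(affine, pts) {
  pts <- as_points_matrix(pts)
  out <- pts %*% t(affine[1:3, 1:3, drop = FALSE])
  sweep(out, 2L, affine[1:3, 4], "+")
}

as_points_matrix <- function(pts) {
  if (is.null(dim(pts))) {
    if (length(pts) != 3L) {
      abort_validation("a point must have exactly 3 coordinates")
    }
    pts <- matrix(pts, nrow = 1L)
  }
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) abort_validation("coordinate matrices must have 3 columns")
  pts
}
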