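#' Tractogram objects
#'
#' A tractogram is an ordered collection of streamlines — 3-D polylines in
#' world RAS millimetres — with optional positive per-streamline weights
#' (e.g., SIFT2-style contributions). Every reader in the package converts
#' into this one canonical space on ingest, so endpoint matching against
#' volumetric masks needs no further bookkeeping.
#'
#' @param streamlines List of n x 3 numeric matrices, each with >= 2 rows.
#' @param weights Optional numeric vector, one positive weight per streamline.
#' @param meta Optional named list of provenance (source format, path, ...).
#' @return An `fsub_tractogram` list with elements `streamlines`, `weights`,
#'   `meta`.
#' @export
tractogram <- function(streamlines, weights = NULL, meta = list()) {
  if (!is.list(streamlines)) abort_validation("streamlines must be a list")
  streamlines <- lapply(streamlines, function(s) {
    s <- as_points_matrix(s)
    if (nrow(s) < 2L) abort_validation("every streamline needs at least 2 points")
    if (any(!is.finite(s))) abort_validation("streamline coordinates must be finite")
    s
  })
  if (!is.null(weights)) {
    weights <- as.double(weights)
    if (length(weights) != length(streamlines)) {
      abort_validation("need exactly one weight per streamline")
    }
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      abort_validation("streamline weights must be positive and finite")
    }
  }
  structure(list(streamlines = streamlines, weights = weights, meta = meta),
            class = "fsub_tractogram")
}

#' @export
print.fsub_tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat(sprintf("<fsub_tractogram> %d streamlines, %d points%s\n",
              length(x$streamlines), np,
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' @export
length.fsub_tractogram <- function(x) length(x$streamlines)

#' Subset a tractogram by streamline index
#'
#' Pure filtering: kept streamlines are returned bit-unchanged, and weights
#' (when present) are subset consistently. Indices are 1-based.
#'
#' @param t A [tractogram()].
#' @param indices Integer vector of 1-based streamline indices.
#' @return A [tractogram()] containing the selected streamlines in the given
#'   order.
#' @export
subset_tractogram <- function(t, indices) {
  indices <- as.integer(indices)
  n <- length(t$streamlines)
  if (length(indices) && (min(indices) < 1L || max(indices) > n)) {
    abort_validation(sprintf("streamline indices must be in [1, %d]", n))
  }
  out <- t
  out$streamlines <- t$streamlines[indices]
  if (!is.null(t$weights)) out$weights <- t$weights[indices]
  out
}

#' Streamline lengths
#'
#' Arc length of each streamline: the sum of its segment lengths, in mm.
#'
#' @param t A [tractogram()].
#' @return Numeric vector of lengths.
#' @export
streamline_lengths <- function(t) {
  vapply(t$streamlines, function(s) {
    sum(row_norms(diff(s)))
  }, double(1))
}

#' Read per-streamline weights from a sidecar text file
#'
#' One positive float per line (blank lines ignored), order-matched to the
#' tractogram it accompanies, as commonly written for SIFT2-style weights.
#'
#' @param path Text file path.
#' @param n_expected Optional expected count; mismatch is an error.
#' @return Numeric vector of weights.
#' @export
read_streamline_weights <- function(path, n_expected = NULL) {
  stopifnot_file_exists(path, "weights file")
  w <- scan(path, what = double(), quiet = TRUE)
  if (!is.null(n_expected) && length(w) != n_expected) {
    abort_corrupt(sprintf("weights file has %d values but tractogram has %d streamlines",
                          length(w), n_expected))
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort_validation("streamline weights must be positive and finite")
  }
  w
}
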