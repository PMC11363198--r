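#' Connectivity profile of an fROI across named bundles
#'
#' For each bundle, counts the streamlines whose endpoints match the fROI
#' mask under the same one-ROI rule used for extraction, and expresses the
#' counts as percentages of the total matched across the supplied bundle set
#' (no whole-tractogram denominator). When every bundle carries weights, a
#' weighted variant summing matched streamline weights is reported too.
#'
#' @param froi A non-empty [binary_mask()] (typically fROI x interface).
#' @param bundles Named list of [tractogram()] objects.
#' @param params A [match_params()]; published validation used a 3 mm radial
#'   search, the package default is 2 mm.
#' @param weighted Use summed streamline weights instead of counts for the
#'   percentages (requires weights on every bundle).
#' @return A `connectivity_profile`: a tibble with columns `bundle`,
#'   `count`, `weighted_count` (NA when unweighted), `percentage`, plus
#'   attributes `total_zero` and `params`.
#' @export
connectivity_profile <- function(froi, bundles, params = match_params(),
                                 weighted = FALSE) {
  if (!any(froi$values == 1)) abort_validation("empty fROI mask")
  if (!is.list(bundles) || length(bundles) < 1L) {
    abort_validation("need at least one bundle")
  }
  if (is.null(names(bundles)) || any(!nzchar(names(bundles)))) {
    abort_validation("bundles must be named")
  }
  counts <- numeric(length(bundles))
  wcounts <- rep(NA_real_, length(bundles))
  have_weights <- all(vapply(bundles, function(b) !is.null(b$weights), logical(1)))
  if (weighted && !have_weights) {
    abort_parameter("weighted profiles need weights on every bundle")
  }
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    if (length(b$streamlines) == 0L) {
      counts[i] <- 0
      if (have_weights) wcounts[i] <- 0
      next
    }
    res <- suppressWarnings(extract_fsub(b, froi, params = params))
    counts[i] <- length(res$selected)
    if (have_weights) wcounts[i] <- sum(b$weights[res$selected])
  }
  basis <- if (weighted) wcounts else counts
  total <- sum(basis)
  total_zero <- total == 0
  pct <- if (total_zero) rep(0, length(bundles)) else 100 * basis / total
  out <- tibble::tibble(bundle = names(bundles), count = as.integer(counts),
                        weighted_count = wcounts, percentage = pct)
  structure(out, total_zero = total_zero, params = params,
            class = c("fsub_profile", class(out)))
}

#' Pearson correlation between two connectivity profiles
#'
#' Profiles must cover the same bundles in the same order and have at least
#' three bundles; a constant profile has no defined correlation and is an
#' error rather than a silent zero.
#'
#' @param p,q `connectivity_profile` objects.
#' @return Pearson's r of the percentage vectors, in `[-1, 1]`.
#' @export
profile_correlation <- function(p, q) {
  if (!identical(p$bundle, q$bundle)) {
    abort_validation("profiles cover different bundle sets (names or order differ)")
  }
  if (nrow(p) < 3L) abort_validation("profile correlation needs at least 3 bundles")
  if (stats::sd(p$percentage) == 0 || stats::sd(q$percentage) == 0) {
    abort_validation("correlation with a constant profile is undefined")
  }
  stats::cor(p$percentage, q$percentage)
}

#' Summary record for an extracted FSuB
#'
#' Reports streamline count, summed weight (the count itself when the
#' tractogram is unweighted, i.e. unit weights), fROI volume in cubic mm
#' (set voxels times voxel volume), streamline count per cubic mm of fROI
#' (the size-bias normalisation), mean streamline length, and the matching
#' parameters used.
#'
#' @param res An `fsub_result` from [extract_fsub()].
#' @param fsub The extracted [tractogram()] (subset of the input).
#' @param froi The fROI [binary_mask()] used for extraction.
#' @return A one-row tibble.
#' @export
fsub_summary <- function(res, fsub, froi) {
  n <- length(fsub$streamlines)
  if (n != length(res$selected)) {
    abort_validation("fsub tractogram does not match the result's selection")
  }
  total_weight <- if (is.null(fsub$weights)) as.double(n) else sum(fsub$weights)
  vol <- mask_volume_mm3(froi)
  tibble::tibble(
    n_streamlines = n,
    total_weight = total_weight,
    froi_volume_mm3 = vol,
    streamlines_per_mm3 = n / vol,
    mean_length_mm = if (n > 0L) mean(streamline_lengths(fsub)) else NA_real_,
    search_type = res$params$search_type,
    search_dist_mm = res$params$search_dist_mm
  )
}
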