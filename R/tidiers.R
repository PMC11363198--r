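#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the endpoint assignments of an extraction
#'
#' @param x An `fsub_result` from [extract_fsub()].
#' @param ... Unused.
#' @return The assignments tibble: one row per matched endpoint with the
#'   streamline index, which end matched, the ROI, the 0-based voxel index,
#'   and the match distance in mm.
#' @method tidy fsub_result
#' @export
tidy.fsub_result <- function(x, ...) {
  x$assignments
}

#' One-row summary of an extraction
#'
#' @param x An `fsub_result`.
#' @param ... Unused.
#' @return A one-row tibble: input and selected streamline counts, selection
#'   fraction, search settings, and warning count.
#' @method glance fsub_result
#' @export
glance.fsub_result <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_selected = length(x$selected),
    fraction_selected = length(x$selected) / x$n_input,
    search_type = x$params$search_type,
    search_dist_mm = x$params$search_dist_mm,
    n_rois = length(x$roi_names),
    n_warnings = length(x$warnings)
  )
}

#' Grouped-bar plot of connectivity profiles
#'
#' @param object A `connectivity_profile` (optionally row-bound with a
#'   `profile` column distinguishing several profiles).
#' @param ... Unused.
#' @return A ggplot: percentage of matched streamlines per bundle.
#' @method autoplot fsub_profile
#' @export
autoplot.fsub_profile <- function(object, ...) {
  df <- as.data.frame(object)
  df$bundle <- factor(df$bundle, levels = unique(df$bundle))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bundle, y = .data$percentage))
  if ("profile" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$profile),
                               position = ggplot2::position_dodge())
  } else {
    p <- p + ggplot2::geom_col(fill = "#0072B2")
  }
  p + ggplot2::labs(x = NULL, y = "% of matched streamlines") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
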