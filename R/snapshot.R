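# Static snapshot rendering. The three orthographic panels (axial, coronal,
# sagittal) are rasterized directly into an RGB array and written with
# png::writePNG, so identical inputs give byte-identical images and overlay
# pixel sets are exactly testable.

PANEL_AXES <- list(axial = c(1L, 2L), coronal = c(1L, 3L), sagittal = c(2L, 3L))

# Map world points into integer pixel coordinates of one panel.
panel_pixels <- function(pts, axes, bbox, size) {
  u <- (pts[, axes[1]] - bbox[1, axes[1]]) / (bbox[2, axes[1]] - bbox[1, axes[1]])
  v <- (pts[, axes[2]] - bbox[1, axes[2]]) / (bbox[2, axes[2]] - bbox[1, axes[2]])
  px <- pmin(pmax(1L + as.integer(floor(u * (size - 1) + 0.5)), 1L), size)
  py <- pmin(pmax(1L + as.integer(floor((1 - v) * (size - 1) + 0.5)), 1L), size)
  cbind(py, px)  # row, column
}

# Densify polylines so drawn segments leave no pixel gaps.
densify <- function(s, step) {
  seg <- diff(s)
  lens <- row_norms(seg)
  pieces <- lapply(seq_len(nrow(seg)), function(i) {
    n <- max(2L, ceiling(lens[i] / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    outer(1 - tt, s[i, ]) + outer(tt, s[i + 1L, ])
  })
  do.call(rbind, pieces)
}

tract_pixel_set <- function(t, axes, bbox, size, step) {
  if (length(t$streamlines) == 0L) return(matrix(integer(0), ncol = 2))
  pts <- do.call(rbind, lapply(t$streamlines, densify, step = step))
  unique(panel_pixels(pts, axes, bbox, size))
}

#' Render a static three-panel snapshot
#'
#' Orthographic axial, coronal, and sagittal projections of the original
#' bundle, the extracted FSuB overlaid on top, and the target fROI voxels,
#' in configurable colors. An empty FSuB still produces an image, with a
#' warning banner rendered along the top edge. A sidecar JSON
#' (`<path>.json`) records the legend: colors, panel order, and dimensions.
#'
#' @param tract The original [tractogram()] (non-empty).
#' @param fsub The extracted FSuB [tractogram()] (may be empty).
#' @param masks A [binary_mask()] or list of masks to draw as fROI voxels.
#' @param path Output PNG path.
#' @param colors Named list with entries `bundle`, `fsub`, `roi` (any R
#'   color specification).
#' @param panel_size Pixel edge length of each square panel.
#' @return Invisibly, a list with the image `path`, `dims`, `colors`, and
#'   per-panel pixel sets for the bundle and FSuB overlays.
#' @export
render_snapshot <- function(tract, fsub, masks, path,
                            colors = list(bundle = "#D55E00",
                                          fsub = "#FFFFFF",
                                          roi = "#0072B2"),
                            panel_size = 256L) {
  if (!inherits(tract, "fsub_tractogram") || length(tract$streamlines) == 0L) {
    abort_validation("snapshot needs a non-empty original tractogram")
  }
  if (inherits(masks, "fsub_mask")) masks <- list(masks)
  size <- as.integer(panel_size)
  all_pts <- do.call(rbind, tract$streamlines)
  centers <- do.call(rbind, lapply(masks, function(m) {
    v <- voxel_centers_mm(m)
    if (nrow(v)) v else NULL
  }))
  ref <- rbind(all_pts, centers)
  bbox <- rbind(apply(ref, 2L, min) - 2, apply(ref, 2L, max) + 2)

  img <- array(0.08, dim = c(size, 3L * size, 3L))  # near-black background
  col3 <- function(cl) as.double(grDevices::col2rgb(cl)) / 255
  paint <- function(pix, offset, cl) {
    if (nrow(pix) == 0L) return(invisible())
    rgbv <- col3(cl)
    for (ch in 1:3) {
      img[cbind(pix[, 1], pix[, 2] + offset, ch)] <<- rgbv[ch]
    }
  }
  step <- min(diff(bbox)) / size  # densification step ~ 1 pixel
  pixel_sets <- list()
  for (pn in names(PANEL_AXES)) {
    axes <- PANEL_AXES[[pn]]
    offset <- (match(pn, names(PANEL_AXES)) - 1L) * size
    roi_pix <- if (is.null(centers)) {
      matrix(integer(0), ncol = 2)
    } else {
      unique(panel_pixels(centers, axes, bbox, size))
    }
    bundle_pix <- tract_pixel_set(tract, axes, bbox, size, step)
    fsub_pix <- tract_pixel_set(fsub, axes, bbox, size, step)
    paint(roi_pix, offset, colors$roi)
    paint(bundle_pix, offset, colors$bundle)
    paint(fsub_pix, offset, colors$fsub)
    pixel_sets[[pn]] <- list(bundle = bundle_pix, fsub = fsub_pix,
                             roi = roi_pix)
  }
  empty_fsub <- length(fsub$streamlines) == 0L
  if (empty_fsub) {
    img[1:8, , 1] <- 0.8; img[1:8, , 2] <- 0.1; img[1:8, , 3] <- 0.1
  }
  png::writePNG(img, path)
  legend <- list(colors = colors, panels = names(PANEL_AXES),
                 width = 3L * size, height = size,
                 warning_banner = empty_fsub)
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(legend, list(path = path, pixel_sets = pixel_sets)))
}
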