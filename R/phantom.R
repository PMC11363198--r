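#' Slab phantom specification
#'
#' Describes a deterministic synthetic dataset on a flat-slab geometry:
#' white matter fills z < 0, cortical gray matter fills
#' 0 <= z < `gm_thickness_mm`, CSF lies above, with analytic partial volumes
#' in straddling voxels. The gray/white boundary mesh is a regular grid
#' triangulation of the z = 0 plane with outward normals (0, 0, 1). Circular
#' "fROI" patches live on that plane; bundles are smooth arcs dipping into
#' the white matter that terminate on (or at a signed offset from) the
#' interface inside their patches; decoys terminate on the interface but at
#' least `decoy_margin_mm` away from the edge of every patch.
#'
#' @param shape Grid dimensions (3 positive integers).
#' @param voxel_mm Voxel edge lengths (scalar or 3-vector, mm).
#' @param gm_thickness_mm Cortical thickness of the slab, mm.
#' @param patches List of [phantom_patch()] definitions.
#' @param bundles List of [phantom_bundle()] definitions.
#' @param n_decoys Number of decoy streamlines.
#' @param decoy_margin_mm Minimum distance from a decoy endpoint to the edge
#'   of any patch; the default 5 mm is more than twice the default 2 mm
#'   search radius, so default-parameter matching has unambiguous truth.
#' @param seed Integer seed; identical seeds give bitwise-identical datasets.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(49L, 49L, 24L), voxel_mm = 1,
                         gm_thickness_mm = 3,
                         patches = list(
                           phantom_patch("A", center = c(-8, 0), radius_mm = 4, peak = 10),
                           phantom_patch("B", center = c(8, 0), radius_mm = 4, peak = 8)),
                         bundles = list(
                           phantom_bundle("target", source = "A", n_streamlines = 100L)),
                         n_decoys = 400L, decoy_margin_mm = 5, seed = 42L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    abort_parameter("shape must be 3 integers >= 4")
  }
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (any(voxel_mm <= 0)) abort_parameter("voxel sizes must be positive")
  if (gm_thickness_mm <= 0) abort_parameter("gm_thickness_mm must be positive")
  pn <- vapply(patches, `[[`, character(1), "name")
  if (anyDuplicated(pn)) abort_parameter("patch names must be unique")
  for (b in bundles) {
    if (!b$source %in% pn) abort_parameter(sprintf("unknown source patch '%s'", b$source))
    if (!is.null(b$sink) && !b$sink %in% pn) {
      abort_parameter(sprintf("unknown sink patch '%s'", b$sink))
    }
  }
  structure(list(shape = shape, voxel_mm = as.double(voxel_mm),
                 gm_thickness_mm = gm_thickness_mm, patches = patches,
                 bundles = bundles, n_decoys = as.integer(n_decoys),
                 decoy_margin_mm = decoy_margin_mm, seed = as.integer(seed)),
            class = "fsub_phantom_spec")
}

#' @rdname phantom_spec
#' @param name Patch / bundle name.
#' @param center Patch centre on the interface plane, (x, y) mm.
#' @param radius_mm Patch radius, mm.
#' @param peak Peak statistic value at the patch centre (the synthetic
#'   statistical map is a sum of radial bumps falling to 0 at twice the
#'   radius).
#' @export
phantom_patch <- function(name, center, radius_mm, peak = 1) {
  if (radius_mm <= 0) abort_parameter("patch radius must be positive")
  list(name = name, center = as.double(center), radius_mm = radius_mm,
       peak = peak)
}

#' @rdname phantom_spec
#' @param source Name of the patch the first endpoint terminates in.
#' @param sink Optional name of the patch the last endpoint terminates in;
#'   `NULL` gives a free end deep in the white matter, far from every patch.
#' @param n_streamlines Number of streamlines in the bundle.
#' @param endpoint_offset_mm Signed distance of termination from the
#'   interface (negative = short of it, inside white matter).
#' @param jitter_sd_mm Gaussian jitter applied to endpoint coordinates.
#' @export
phantom_bundle <- function(name, source, sink = NULL, n_streamlines = 100L,
                           endpoint_offset_mm = 0, jitter_sd_mm = 0) {
  if (n_streamlines < 0L) abort_parameter("n_streamlines must be >= 0")
  if (jitter_sd_mm < 0) abort_parameter("jitter_sd_mm must be >= 0")
  list(name = name, source = source, sink = sink,
       n_streamlines = as.integer(n_streamlines),
       endpoint_offset_mm = endpoint_offset_mm, jitter_sd_mm = jitter_sd_mm)
}

#' Build a slab phantom dataset
#'
#' Deterministic given `spec$seed`. Returns every object the pipeline
#' consumes — mesh, five-tissue segmentation, per-vertex statistic map,
#' per-patch labels, named bundle tractograms plus a combined tractogram —
#' together with a per-streamline ground-truth table.
#'
#' @param spec A [phantom_spec()].
#' @return An `fsub_phantom` list with elements `mesh`, `seg`, `statmap`,
#'   `labels`, `bundles`, `tractogram`, `truth` (tibble: `streamline`,
#'   `bundle`, `source_patch`, `sink_patch`, `is_decoy`), `grid`, `spec`.
#' @export
make_slab_phantom <- function(spec = phantom_spec()) {
  withr::with_seed(spec$seed, make_slab_phantom_impl(spec))
}

make_slab_phantom_impl <- function(spec) {
  vs <- spec$voxel_mm
  dm <- spec$shape
  # z = 0 must sit at a voxel centre so the interface layer mixes 50/50.
  kz0 <- as.integer(round(dm[3] * 2 / 3))
  affine <- diag(4)
  affine[1, 1] <- vs[1]; affine[2, 2] <- vs[2]; affine[3, 3] <- vs[3]
  affine[1:3, 4] <- c(-(dm[1] - 1) / 2 * vs[1], -(dm[2] - 1) / 2 * vs[2],
                      -kz0 * vs[3])
  grid <- volume_image(array(0, dim = dm), affine)

  # Analytic partial volumes from each voxel's z-extent.
  zc <- ((0:(dm[3] - 1)) - kz0) * vs[3]
  h <- vs[3]
  overlap <- function(lo, hi) pmin(pmax((pmin(hi, zc + h / 2) - pmax(lo, zc - h / 2)) / h, 0), 1)
  wm_z <- overlap(-Inf, 0)
  gm_z <- overlap(0, spec$gm_thickness_mm)
  csf_z <- overlap(spec$gm_thickness_mm, Inf)
  plane <- function(fz) array(rep(fz, each = dm[1] * dm[2]), dim = dm)
  zeros <- array(0, dim = dm)
  seg <- tissue_segmentation(list(plane(gm_z), zeros, plane(wm_z),
                                  plane(csf_z), zeros), affine)

  # Boundary mesh: regular lattice on z = 0, counter-clockwise winding seen
  # from +z so outward normals point (0, 0, 1) into the gray matter.
  ext <- c(floor((dm[1] - 1) / 2 * vs[1]) - 2, floor((dm[2] - 1) / 2 * vs[2]) - 2)
  xs <- seq(-ext[1], ext[1], by = 1)
  ys <- seq(-ext[2], ext[2], by = 1)
  gv <- expand.grid(x = xs, y = ys)
  vertices <- cbind(gv$x, gv$y, 0)
  nx <- length(xs)
  ny <- length(ys)
  vid <- function(i, j) (j - 1L) * nx + i
  f1 <- f2 <- matrix(0L, nrow = (nx - 1L) * (ny - 1L), ncol = 3L)
  r <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      f1[r, ] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
      f2[r, ] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      r <- r + 1L
    }
  }
  mesh <- surface_mesh(vertices, rbind(f1, f2), space_tag = "world")

  # Patch geometry checks, statistic map, and labels.
  for (p in spec$patches) {
    if (any(abs(p$center) + p$radius_mm > ext)) {
      abort_parameter(sprintf("patch '%s' extends beyond the mesh", p$name))
    }
  }
  statmap <- numeric(nrow(vertices))
  labels <- list()
  for (p in spec$patches) {
    d <- sqrt((vertices[, 1] - p$center[1])^2 + (vertices[, 2] - p$center[2])^2)
    statmap <- statmap + p$peak * pmax(0, 1 - d / (2 * p$radius_mm))
    labels[[p$name]] <- vertex_label(which(d <= p$radius_mm),
                                     values = statmap[d <= p$radius_mm],
                                     coords = vertices[d <= p$radius_mm, , drop = FALSE])
  }

  patch_by_name <- stats::setNames(spec$patches,
                                   vapply(spec$patches, `[[`, character(1), "name"))
  sample_in_patch <- function(p) {
    u <- stats::runif(1)
    th <- stats::runif(1, 0, 2 * pi)
    rr <- 0.7 * p$radius_mm * sqrt(u)
    p$center + rr * c(cos(th), sin(th))
  }
  clear_of_patches <- function(xy, margin) {
    all(vapply(spec$patches, function(p) {
      sqrt(sum((xy - p$center)^2)) - p$radius_mm >= margin
    }, logical(1)))
  }
  sample_far_point <- function(margin) {
    for (try in 1:2000) {
      xy <- c(stats::runif(1, -ext[1], ext[1]), stats::runif(1, -ext[2], ext[2]))
      if (clear_of_patches(xy, margin)) return(xy)
    }
    abort_parameter("patches leave no room for decoys at the requested margin")
  }
  bezier_arc <- function(p0, p2) {
    chord <- sqrt(sum((p2 - p0)^2))
    dip <- min(8, max(2, chord / 2))
    p1 <- (p0 + p2) / 2
    p1[3] <- -dip
    npts <- max(3L, as.integer(ceiling(chord / 0.5)))
    tt <- seq(0, 1, length.out = npts)
    outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  }

  all_streamlines <- list()
  truth_rows <- list()
  bundles_out <- list()
  global <- 0L
  for (b in spec$bundles) {
    sl <- vector("list", b$n_streamlines)
    for (i in seq_len(b$n_streamlines)) {
      src <- patch_by_name[[b$source]]
      p0 <- c(sample_in_patch(src), b$endpoint_offset_mm)
      if (!is.null(b$sink)) {
        p2 <- c(sample_in_patch(patch_by_name[[b$sink]]), b$endpoint_offset_mm)
      } else {
        p2 <- c(sample_far_point(spec$decoy_margin_mm), -8)
      }
      if (b$jitter_sd_mm > 0) {
        p0 <- p0 + stats::rnorm(3, sd = b$jitter_sd_mm)
        p2 <- p2 + stats::rnorm(3, sd = b$jitter_sd_mm)
      }
      sl[[i]] <- bezier_arc(p0, p2)
    }
    bundles_out[[b$name]] <- tractogram(sl, meta = list(seed = spec$seed))
    if (b$n_streamlines > 0L) {
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        streamline = global + seq_len(b$n_streamlines),
        bundle = b$name, source_patch = b$source,
        sink_patch = if (is.null(b$sink)) NA_character_ else b$sink,
        is_decoy = FALSE)
    }
    all_streamlines <- c(all_streamlines, sl)
    global <- global + b$n_streamlines
  }
  if (spec$n_decoys > 0L) {
    sl <- vector("list", spec$n_decoys)
    for (i in seq_len(spec$n_decoys)) {
      repeat {
        p0 <- c(sample_far_point(spec$decoy_margin_mm), 0)
        p2 <- c(sample_far_point(spec$decoy_margin_mm), 0)
        if (sqrt(sum((p2 - p0)^2)) >= 3) break
      }
      sl[[i]] <- bezier_arc(p0, p2)
    }
    bundles_out[["decoys"]] <- tractogram(sl, meta = list(seed = spec$seed))
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      streamline = global + seq_len(spec$n_decoys),
      bundle = "decoys", source_patch = NA_character_,
      sink_patch = NA_character_, is_decoy = TRUE)
    all_streamlines <- c(all_streamlines, sl)
    global <- global + spec$n_decoys
  }
  truth <- if (length(truth_rows)) {
    dplyr::bind_rows(truth_rows)
  } else {
    tibble::tibble(streamline = integer(0), bundle = character(0),
                   source_patch = character(0), sink_patch = character(0),
                   is_decoy = logical(0))
  }
  combined <- tractogram(all_streamlines, meta = list(seed = spec$seed))

  structure(list(mesh = mesh, seg = seg, statmap = statmap, labels = labels,
                 bundles = bundles_out, tractogram = combined, truth = truth,
                 grid = grid, spec = spec),
            class = "fsub_phantom")
}

#' @export
print.fsub_phantom <- function(x, ...) {
  cat(sprintf("<fsub_phantom> %d patches, %d bundles, %d streamlines, grid %s\n",
              length(x$labels), length(x$bundles),
              length(x$tractogram$streamlines),
              paste(x$spec$shape, collapse = "x")))
  invisible(x)
}

#' Precision and recall of an extraction against phantom truth
#'
#' @param truth The phantom `truth` tibble (or an integer vector of
#'   true-positive streamline indices).
#' @param result An `fsub_result` over the same (combined) tractogram.
#' @return A one-row tibble: `precision`, `recall`, `n_selected`, `n_true`,
#'   and `undefined_precision` (TRUE when nothing was selected against a
#'   non-empty truth; precision is then reported as 0).
#' @export
evaluate_recovery <- function(truth, result) {
  positives <- if (is.numeric(truth)) {
    as.integer(truth)
  } else {
    truth$streamline[!truth$is_decoy]
  }
  sel <- result$selected
  tp <- length(intersect(sel, positives))
  undefined <- FALSE
  precision <- if (length(sel) == 0L) {
    if (length(positives) == 0L) 1 else { undefined <- TRUE; 0 }
  } else {
    tp / length(sel)
  }
  recall <- if (length(positives) == 0L) 1 else tp / length(positives)
  tibble::tibble(precision = precision, recall = recall,
                 n_selected = length(sel), n_true = length(positives),
                 undefined_precision = undefined)
}

#' Write a phantom dataset as a BIDS-like fixture tree
#'
#' Serialises everything through the package's own writers: the 5tt NIfTI,
#' the boundary surface, per-patch `.label` files, the per-vertex statistic
#' map as plain text, each bundle (and the combined tractogram) as TCK and
#' TRK, unit weights, and the truth table as tab-separated text.
#'
#' @param phantom An `fsub_phantom`.
#' @param dir Output directory (created if needed).
#' @param subject Subject tag used in file names.
#' @return Tibble manifest of written files, invisibly.
#' @export
write_phantom_dataset <- function(phantom, dir, subject = "phantom01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(dir, sprintf("sub-%s", subject))
  files <- character(0)
  roles <- character(0)
  add <- function(path, role) {
    files <<- c(files, path); roles <<- c(roles, role)
  }
  p <- paste0(pre, "_desc-5tt.nii"); write_5tt(phantom$seg, p); add(p, "5tt")
  p <- paste0(pre, "_hemi-lh_white.surf"); write_fs_surface(phantom$mesh, p); add(p, "surface")
  p <- paste0(pre, "_statmap.txt")
  writeLines(sprintf("%.10g", phantom$statmap), p); add(p, "statmap")
  for (nm in names(phantom$labels)) {
    p <- paste0(pre, sprintf("_desc-%s.label", nm))
    write_label(phantom$labels[[nm]], p, mesh = phantom$mesh); add(p, "label")
  }
  for (nm in names(phantom$bundles)) {
    b <- phantom$bundles[[nm]]
    if (length(b$streamlines) == 0L) next
    p <- paste0(pre, sprintf("_bundle-%s_tractography.tck", nm))
    write_tck(b, p); add(p, "bundle_tck")
    p <- paste0(pre, sprintf("_bundle-%s_tractography.trk", nm))
    write_trk(b, p, reference = phantom$grid); add(p, "bundle_trk")
  }
  p <- paste0(pre, "_desc-combined_tractography.tck")
  write_tck(phantom$tractogram, p); add(p, "tractogram")
  p <- paste0(pre, "_weights.txt")
  writeLines(sprintf("%.10g", rep(1, length(phantom$tractogram$streamlines))), p)
  add(p, "weights")
  p <- paste0(pre, "_truth.tsv")
  utils::write.table(phantom$truth, p, sep = "\t", row.names = FALSE, quote = FALSE)
  add(p, "truth")
  invisible(tibble::tibble(path = files, role = roles))
}
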