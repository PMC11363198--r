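#' Projection parameters
#'
#' Controls how surface labels are carried into the volume (and volumes
#' sampled onto the surface) along inward vertex normals. `inward_depth_mm`
#' is of the order of cortical thickness so the swept segment reaches the
#' gray/white interface beneath each vertex; `step_mm` at a quarter of a
#' typical voxel edge avoids holes in the voxelization.
#'
#' @param inward_depth_mm Depth swept inward from each vertex, mm (>= 0).
#' @param step_mm Sampling step along the segment, mm (> 0).
#' @param combine How multiple samples along the segment combine for
#'   volume-to-surface sampling: `"max"` or `"mean"`.
#' @return A `projection_params` list.
#' @export
projection_params <- function(inward_depth_mm = 2.0, step_mm = 0.25,
                              combine = c("max", "mean")) {
  combine <- match.arg(combine)
  if (!is_scalar_number(inward_depth_mm) || inward_depth_mm < 0) {
    abort_parameter("inward_depth_mm must be a non-negative number")
  }
  if (!is_scalar_number(step_mm) || step_mm <= 0) {
    abort_parameter("step_mm must be a positive number")
  }
  if (inward_depth_mm > 0 && step_mm > inward_depth_mm) {
    abort_parameter("step_mm must not exceed inward_depth_mm")
  }
  structure(list(inward_depth_mm = inward_depth_mm, step_mm = step_mm,
                 combine = combine),
            class = "fsub_projection_params")
}

projection_depths <- function(params) {
  if (params$inward_depth_mm == 0) return(0)
  unique(c(seq(0, params$inward_depth_mm, by = params$step_mm),
           params$inward_depth_mm))
}

#' Per-vertex outward unit normals
#'
#' The normal at a vertex is the normalized sum of incident face normals
#' weighted by face area (the unnormalized triangle cross products sum to
#' exactly that). Outward means consistent with counter-clockwise face
#' winding. Isolated vertices get a zero normal and a warning.
#'
#' @param mesh A [surface_mesh()].
#' @return An n x 3 matrix of unit (or zero) vectors.
#' @export
compute_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  normals <- matrix(0, nrow = nrow(v), ncol = 3L)
  if (nrow(f) > 0L) {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    for (corner in 1:3) {
      for (ax in 1:3) {
        acc <- rowsum(fn[, ax], f[, corner])
        idx <- as.integer(rownames(acc))
        normals[idx, ax] <- normals[idx, ax] + acc[, 1]
      }
    }
  }
  nrm <- row_norms(normals)
  isolated <- nrm == 0
  if (any(isolated)) {
    fsub_warn(sprintf("%d vertices have no incident face (zero normal): %s",
                      sum(isolated),
                      paste(utils::head(which(isolated), 10L), collapse = ", ")))
  }
  normals[!isolated, ] <- normals[!isolated, , drop = FALSE] / nrm[!isolated]
  normals
}

#' Sample a volume at mesh vertices
#'
#' The native analogue of vol2surf: each vertex is sampled at positions
#' `v - d * n` for depths `d` from 0 to `inward_depth_mm` in steps of
#' `step_mm` (n the outward unit normal), and the samples are combined with
#' `params$combine`. Samples falling outside the grid contribute 0 and the
#' vertex is flagged missing if all its samples fall outside.
#'
#' @param vol A [volume_image()].
#' @param mesh A [surface_mesh()] in world space.
#' @param params A [projection_params()].
#' @param interp `"nearest"` or `"trilinear"`.
#' @return A list with `values` (one per vertex) and `missing` (logical).
#' @export
sample_volume_at_vertices <- function(vol, mesh, params = projection_params(),
                                      interp = c("nearest", "trilinear")) {
  interp <- match.arg(interp)
  mesh <- surface_to_world(mesh)
  normals <- compute_vertex_normals(mesh)
  depths <- projection_depths(params)
  dm <- dim(vol$values)
  nv <- nrow(mesh$vertices)

  vox_all <- world_to_voxel(vol, mesh$vertices)
  if (!any(vox_all[, 1] > -0.5 & vox_all[, 1] < dm[1] - 0.5 &
           vox_all[, 2] > -0.5 & vox_all[, 2] < dm[2] - 0.5 &
           vox_all[, 3] > -0.5 & vox_all[, 3] < dm[3] - 0.5)) {
    abort_space("every vertex lies outside the volume grid; mesh and volume are probably in different spaces")
  }

  samples <- matrix(0, nrow = nv, ncol = length(depths))
  inside_any <- matrix(FALSE, nrow = nv, ncol = length(depths))
  for (k in seq_along(depths)) {
    pts <- mesh$vertices - depths[k] * normals
    res <- sample_volume_points(vol, pts, interp)
    samples[, k] <- res$values
    inside_any[, k] <- res$inside
  }
  combined <- switch(params$combine,
    max = apply(samples, 1L, max),
    mean = rowMeans(samples))
  list(values = combined, missing = !apply(inside_any, 1L, any))
}

# Sample a volume at world points; outside-grid points give 0 / inside=FALSE.
sample_volume_points <- function(vol, pts, interp) {
  dm <- dim(vol$values)
  vox <- world_to_voxel(vol, pts)
  vals <- numeric(nrow(vox))
  if (interp == "nearest") {
    idx <- round(vox)
    inside <- idx[, 1] >= 0 & idx[, 1] < dm[1] &
              idx[, 2] >= 0 & idx[, 2] < dm[2] &
              idx[, 3] >= 0 & idx[, 3] < dm[3]
    if (any(inside)) {
      lin <- idx[inside, 1] + dm[1] * (idx[inside, 2] + dm[2] * idx[inside, 3]) + 1
      vals[inside] <- vol$values[lin]
    }
  } else {
    # Trilinear: requires the full 8-voxel neighbourhood in-grid.
    f <- floor(vox)
    w <- vox - f
    inside <- f[, 1] >= 0 & f[, 1] + 1 < dm[1] &
              f[, 2] >= 0 & f[, 2] + 1 < dm[2] &
              f[, 3] >= 0 & f[, 3] + 1 < dm[3]
    if (any(inside)) {
      fi <- f[inside, , drop = FALSE]
      wi <- w[inside, , drop = FALSE]
      acc <- numeric(sum(inside))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        lin <- (fi[, 1] + dx) + dm[1] * ((fi[, 2] + dy) + dm[2] * (fi[, 3] + dz)) + 1
        wt <- (if (dx) wi[, 1] else 1 - wi[, 1]) *
              (if (dy) wi[, 2] else 1 - wi[, 2]) *
              (if (dz) wi[, 3] else 1 - wi[, 3])
        acc <- acc + wt * vol$values[lin]
      }
      vals[inside] <- acc
    }
  }
  list(values = vals, inside = inside)
}

#' Project a vertex label into a volume grid
#'
#' The native analogue of surf2vol: a voxel is set iff the inward segment
#' `[v, v - depth * n]` of some labelled vertex, discretized at `step_mm`,
#' passes through it. There is no radial dilation — projection follows the
#' normals only, so the fROI's footprint is not overestimated.
#'
#' @param mesh A [surface_mesh()] in world space (tkr meshes are shifted).
#' @param label A [vertex_label()] bound to `mesh`.
#' @param grid A [volume_image()] defining the output grid.
#' @param params A [projection_params()].
#' @return A [binary_mask()] on the same grid as `grid`.
#' @export
project_label_to_volume <- function(mesh, label, grid,
                                    params = projection_params()) {
  validate_label_on_mesh(label, mesh)
  if (length(label$vertex_indices) == 0L) abort_validation("empty fROI label")
  mesh <- surface_to_world(mesh)
  normals <- compute_vertex_normals(mesh)
  depths <- projection_depths(params)
  verts <- mesh$vertices[label$vertex_indices, , drop = FALSE]
  norms <- normals[label$vertex_indices, , drop = FALSE]
  dm <- dim(grid$values)
  mask <- array(0, dim = dm)
  seen_inside <- FALSE
  for (d in depths) {
    vox <- round(world_to_voxel(grid, verts - d * norms))
    inside <- vox[, 1] >= 0 & vox[, 1] < dm[1] &
              vox[, 2] >= 0 & vox[, 2] < dm[2] &
              vox[, 3] >= 0 & vox[, 3] < dm[3]
    if (any(inside)) {
      seen_inside <- TRUE
      lin <- vox[inside, 1] + dm[1] * (vox[inside, 2] + dm[2] * vox[inside, 3]) + 1
      mask[lin] <- 1
    }
  }
  if (!seen_inside) {
    abort_space("no labelled vertex projects inside the volume grid")
  }
  binary_mask(mask, grid$affine)
}

#' Threshold a surface statistic within a search space
#'
#' Finds the nearest-rank percentile of the statistic restricted to the
#' search-space vertices and returns the vertices with values strictly
#' greater than that threshold — the top-X% construction used to turn
#' statistical maps into fROIs (with `value_percentile = 90` selecting the
#' top 10% of vertices).
#'
#' @param stat Numeric vector, one statistic per mesh vertex.
#' @param searchspace A [vertex_label()] naming the candidate vertices.
#' @param value_percentile Percentile in `[0, 100)`.
#' @return A [vertex_label()] of selected vertices carrying their statistic
#'   values; empty (with a warning) when the map is constant on the search
#'   space, since strict inequality then selects nothing.
#' @export
threshold_percentile <- function(stat, searchspace, value_percentile = 90) {
  if (!is_scalar_number(value_percentile) ||
      value_percentile < 0 || value_percentile >= 100) {
    abort_parameter("value_percentile must lie in [0, 100)")
  }
  idx <- searchspace$vertex_indices
  if (length(idx) == 0L) abort_validation("empty search space")
  if (max(idx) > length(stat)) {
    abort_validation("search space indexes vertices beyond the statistic map")
  }
  vals <- stat[idx]
  n <- length(vals)
  rank <- max(1L, as.integer(ceiling(value_percentile / 100 * n)))
  thresh <- sort(vals)[rank]
  keep <- vals > thresh
  if (!any(keep)) {
    fsub_warn("no vertex exceeds the percentile threshold (constant map in search space?); returning an empty fROI")
  }
  vertex_label(idx[keep], values = vals[keep], hemisphere = searchspace$hemisphere)
}
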