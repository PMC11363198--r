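#' Endpoint matching parameters
#'
#' `search_type = "radial"` assigns an endpoint to the nearest set-voxel
#' centre within `search_dist_mm` (default 2 mm); `"forward"` marches beyond
#' the endpoint along the terminal tangent in `forward_step_mm` steps until a
#' set voxel is hit or the distance budget is exhausted; `"endpoint"`
#' requires the endpoint itself to lie inside a set voxel.
#'
#' @param search_type One of `"radial"`, `"forward"`, `"endpoint"`.
#' @param search_dist_mm Search budget in mm (>= 0; 0 only with
#'   `"endpoint"`).
#' @param forward_step_mm March step for forward search, mm.
#' @param small_fsub_floor Warn when a non-empty extraction selects at most
#'   this many streamlines (tiny sub-bundles are rarely interpretable); a
#'   warning only, never a filter.
#' @return A `match_params` list.
#' @export
match_params <- function(search_type = c("radial", "forward", "endpoint"),
                         search_dist_mm = 2.0, forward_step_mm = 0.5,
                         small_fsub_floor = 5L) {
  search_type <- match.arg(search_type)
  if (!is_scalar_number(search_dist_mm) || search_dist_mm < 0) {
    abort_parameter("search_dist_mm must be a non-negative number")
  }
  if (search_dist_mm == 0 && search_type != "endpoint") {
    abort_parameter("search_dist_mm = 0 is only meaningful with search_type = 'endpoint'")
  }
  if (!is_scalar_number(forward_step_mm) || forward_step_mm <= 0) {
    abort_parameter("forward_step_mm must be positive")
  }
  structure(list(search_type = search_type,
                 search_dist_mm = search_dist_mm,
                 forward_step_mm = forward_step_mm,
                 small_fsub_floor = as.integer(small_fsub_floor)),
            class = "fsub_match_params")
}

#' Spatial index over the set voxels of a mask
#'
#' Buckets the world-mm centres of set voxels into a uniform grid of cells
#' so nearest-within-radius queries inspect only nearby voxels. Query
#' results are identical to a brute-force scan over all set-voxel centres;
#' ties at equal distance break to the lexicographically smallest
#' (i, j, k) voxel index.
#'
#' @param mask A non-empty [binary_mask()].
#' @return An `fsub_voxel_index` object for [query_voxel_index()].
#' @export
build_voxel_index <- function(mask) {
  ijk <- nonzero_voxels(mask)
  if (nrow(ijk) == 0L) abort_validation("empty target mask")
  centers <- voxel_centers_mm(mask, ijk)
  cell_size <- max(sqrt(colSums(unclass(mask$affine)[1:3, 1:3]^2)))
  cells <- floor(sweep(centers, 2L, cell_size, "/"))
  key <- paste(cells[, 1], cells[, 2], cells[, 3])
  buckets <- split(seq_len(nrow(centers)), key)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(buckets))
  for (k in names(buckets)) assign(k, buckets[[k]], envir = env)
  structure(list(ijk = ijk, centers = centers, cell_size = cell_size,
                 buckets = env, mask = mask),
            class = "fsub_voxel_index")
}

#' Nearest set voxel within a radius
#'
#' @param index An [build_voxel_index()] object.
#' @param points n x 3 world-mm query points.
#' @param radius Search radius, mm (inclusive).
#' @return A tibble with one row per query: `voxel_i/j/k` (0-based, `NA`
#'   when no voxel lies within `radius`) and `distance_mm`.
#' @export
query_voxel_index <- function(index, points, radius) {
  points <- as_points_matrix(points)
  cs <- index$cell_size
  n <- nrow(points)
  out_ijk <- matrix(NA_real_, nrow = n, ncol = 3L)
  out_dist <- rep(NA_real_, n)
  lo <- floor((points - radius) / cs)
  hi <- floor((points + radius) / cs)
  for (q in seq_len(n)) {
    cand <- integer(0)
    for (cx in lo[q, 1]:hi[q, 1]) {
      for (cy in lo[q, 2]:hi[q, 2]) {
        for (cz in lo[q, 3]:hi[q, 3]) {
          b <- get0(paste(cx, cy, cz), envir = index$buckets)
          if (!is.null(b)) cand <- c(cand, b)
        }
      }
    }
    if (length(cand) == 0L) next
    d2 <- rowSums((index$centers[cand, , drop = FALSE] -
                     matrix(points[q, ], length(cand), 3L, byrow = TRUE))^2)
    dmin <- sqrt(min(d2))
    if (dmin > radius) next
    best <- cand[d2 == min(d2)]
    # Candidates (and so `best`) follow the lexicographic order of `ijk`.
    best <- min(best)
    out_ijk[q, ] <- index$ijk[best, ]
    out_dist[q] <- dmin
  }
  tibble::tibble(voxel_i = out_ijk[, 1], voxel_j = out_ijk[, 2],
                 voxel_k = out_ijk[, 3], distance_mm = out_dist)
}

# Reference implementation for the spatial index: all-pairs scan.
brute_force_nearest <- function(mask, points, radius) {
  ijk <- nonzero_voxels(mask)
  centers <- voxel_centers_mm(mask, ijk)
  points <- as_points_matrix(points)
  n <- nrow(points)
  out_ijk <- matrix(NA_real_, nrow = n, ncol = 3L)
  out_dist <- rep(NA_real_, n)
  for (q in seq_len(n)) {
    d2 <- rowSums(sweep(centers, 2L, points[q, ])^2)
    dmin <- sqrt(min(d2))
    if (dmin <= radius) {
      best <- min(which(d2 == min(d2)))
      out_ijk[q, ] <- ijk[best, ]
      out_dist[q] <- dmin
    }
  }
  tibble::tibble(voxel_i = out_ijk[, 1], voxel_j = out_ijk[, 2],
                 voxel_k = out_ijk[, 3], distance_mm = out_dist)
}

#' Match one streamline endpoint to a target mask
#'
#' @param streamline An n x 3 matrix of world-mm points.
#' @param which_end `"first"` or `"last"`.
#' @param index A [build_voxel_index()] over the target mask.
#' @param params A [match_params()].
#' @return A one-row tibble: `which_end`, `matched`, `voxel_i/j/k`
#'   (0-based), `distance_mm`.
#' @export
match_endpoint <- function(streamline, which_end = c("first", "last"),
                           index, params = match_params()) {
  which_end <- match.arg(which_end)
  streamline <- as_points_matrix(streamline)
  n <- nrow(streamline)
  ep <- if (which_end == "first") streamline[1, ] else streamline[n, ]
  neighbor <- if (which_end == "first") streamline[2, ] else streamline[n - 1, ]
  res <- switch(params$search_type,
    radial = {
      q <- query_voxel_index(index, ep, params$search_dist_mm)
      list(ijk = c(q$voxel_i, q$voxel_j, q$voxel_k), dist = q$distance_mm)
    },
    endpoint = {
      if (points_in_mask(index$mask, ep)) {
        vox <- round(world_to_voxel(index$mask, ep))
        list(ijk = as.double(vox), dist = 0)
      } else {
        list(ijk = rep(NA_real_, 3), dist = NA_real_)
      }
    },
    forward = {
      tangent <- ep - neighbor
      tl <- sqrt(sum(tangent^2))
      if (tl == 0) {
        # Degenerate terminal tangent: fall back to radial for this endpoint.
        fsub_warn("coincident terminal points; falling back to radial search for this endpoint")
        q <- query_voxel_index(index, ep, params$search_dist_mm)
        list(ijk = c(q$voxel_i, q$voxel_j, q$voxel_k), dist = q$distance_mm)
      } else {
        tangent <- tangent / tl
        hit <- list(ijk = rep(NA_real_, 3), dist = NA_real_)
        k <- 0L
        repeat {
          d <- k * params$forward_step_mm
          if (d > params$search_dist_mm) break
          pos <- ep + d * tangent
          if (points_in_mask(index$mask, pos)) {
            vox <- round(world_to_voxel(index$mask, pos))
            hit <- list(ijk = as.double(vox), dist = d)
            break
          }
          k <- k + 1L
        }
        hit
      }
    })
  tibble::tibble(which_end = which_end, matched = !is.na(res$dist),
                 voxel_i = res$ijk[1], voxel_j = res$ijk[2],
                 voxel_k = res$ijk[3], distance_mm = res$dist)
}

#' Extract the functional sub-bundle of a tractogram
#'
#' One-ROI mode selects every streamline with at least one endpoint matching
#' the target mask (typically the fROI intersected with the gray/white
#' interface). Two-ROI mode selects streamlines that connect the two
#' targets: one endpoint must match `roi1` and the *other* endpoint `roi2`,
#' in either orientation — a single endpoint matching both masks does not
#' qualify on its own.
#'
#' @param t A [tractogram()] in the masks' world space.
#' @param roi1 A non-empty [binary_mask()].
#' @param roi2 Optional second [binary_mask()] on the same grid.
#' @param params A [match_params()].
#' @param roi_names Character names used in the assignments table.
#' @return An `fsub_result` with fields `selected` (sorted 1-based
#'   streamline indices), `assignments` (tibble: `streamline`, `which_end`,
#'   `roi`, voxel indices, `distance_mm`), `n_input`, `roi_names`, `params`,
#'   and `warnings`.
#' @export
extract_fsub <- function(t, roi1, roi2 = NULL, params = match_params(),
                         roi_names = c("roi1", "roi2")) {
  if (!inherits(t, "fsub_tractogram")) abort_validation("extract_fsub needs a tractogram")
  if (length(t$streamlines) == 0L) abort_validation("empty tractogram")
  if (!any(roi1$values == 1)) abort_validation("roi1 mask is empty")
  two_roi <- !is.null(roi2)
  if (two_roi) {
    if (!any(roi2$values == 1)) abort_validation("roi2 mask is empty")
    if (!same_grid(roi1, roi2)) {
      abort_space("roi1 and roi2 are not on the same grid")
    }
  }
  warnings <- character(0)
  idx1 <- build_voxel_index(roi1)
  idx2 <- if (two_roi) build_voxel_index(roi2) else NULL

  match_both_ends <- function(index, roi_name) {
    rows <- vector("list", length(t$streamlines))
    for (i in seq_along(t$streamlines)) {
      s <- t$streamlines[[i]]
      a <- withCallingHandlers(
        rbind(match_endpoint(s, "first", index, params),
              match_endpoint(s, "last", index, params)),
        fsub_warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          rlang::cnd_muffle(w)
        })
      a$streamline <- i
      a$roi <- roi_name
      rows[[i]] <- a
    }
    dplyr::bind_rows(rows)
  }

  a1 <- match_both_ends(idx1, roi_names[1])
  if (!two_roi) {
    sel_tbl <- a1[a1$matched, , drop = FALSE]
    selected <- sort(unique(sel_tbl$streamline))
  } else {
    a2 <- match_both_ends(idx2, roi_names[2])
    m1 <- matrix(a1$matched, ncol = 2L, byrow = TRUE)  # cols: first, last
    m2 <- matrix(a2$matched, ncol = 2L, byrow = TRUE)
    fwd <- m1[, 1] & m2[, 2]   # first end -> roi1, last end -> roi2
    rev <- m2[, 1] & m1[, 2]
    selected <- which(fwd | rev)
    keep <- logical(nrow(a1))
    for (i in selected) {
      r <- 2L * (i - 1L)
      if (fwd[i]) keep[r + 1L] <- TRUE else keep[r + 2L] <- TRUE
    }
    keep2 <- logical(nrow(a2))
    for (i in selected) {
      r <- 2L * (i - 1L)
      if (fwd[i]) keep2[r + 2L] <- TRUE else keep2[r + 1L] <- TRUE
    }
    sel_tbl <- dplyr::bind_rows(a1[keep, , drop = FALSE], a2[keep2, , drop = FALSE])
  }
  n_sel <- length(selected)
  if (n_sel > 0L && n_sel <= params$small_fsub_floor) {
    msg <- sprintf("very small FSuB (%d streamline%s); interpret with caution",
                   n_sel, if (n_sel == 1L) "" else "s")
    warnings <- c(warnings, msg)
    fsub_warn(msg, class = "fsub_small_fsub_warning")
  }
  assignments <- sel_tbl[order(sel_tbl$streamline, sel_tbl$roi, sel_tbl$which_end),
                         c("streamline", "which_end", "roi",
                           "voxel_i", "voxel_j", "voxel_k", "distance_mm")]
  structure(list(selected = as.integer(selected),
                 assignments = tibble::as_tibble(assignments),
                 n_input = length(t$streamlines),
                 roi_names = roi_names[seq_len(1L + two_roi)],
                 params = params,
                 warnings = unique(warnings)),
            class = "fsub_result")
}

#' @export
print.fsub_result <- function(x, ...) {
  cat(sprintf("<fsub_result> %d / %d streamlines matched (%s, %s search, %.3g mm)\n",
              length(x$selected), x$n_input,
              paste(x$roi_names, collapse = " <-> "),
              x$params$search_type, x$params$search_dist_mm))
  invisible(x)
}
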