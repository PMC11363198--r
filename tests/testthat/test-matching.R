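# Spatial index, endpoint matching semantics, and FSuB extraction.

test_that("querying a single set voxel at its centre returns distance 0", {
  m <- mask_from_voxels(cbind(3, 4, 5))
  idx <- build_voxel_index(m)
  q <- query_voxel_index(idx, c(3, 4, 5), 2)
  expect_equal(c(q$voxel_i, q$voxel_j, q$voxel_k), c(3, 4, 5))
  expect_equal(q$distance_mm, 0)
  far <- query_voxel_index(idx, c(9, 9, 9), 2)
  expect_true(is.na(far$distance_mm))
  expect_error(build_voxel_index(mask_from_voxels(matrix(numeric(0), ncol = 3))),
               class = "fsub_validation_error")
})

test_that("index queries equal the brute-force all-pairs scan", {
  withr::with_seed(21, {
    arr <- array(0, dim = c(12, 12, 12))
    arr[sample(12^3, 150)] <- 1
    aff <- diag(c(1.2, 0.9, 1.5, 1)); aff[1:3, 4] <- c(-3, 2, -7)
    m <- binary_mask(arr, aff)
    pts <- cbind(stats::runif(500, -5, 12), stats::runif(500, 0, 14),
                 stats::runif(500, -9, 12))
    for (r in c(0.8, 2, 4)) {
      a <- query_voxel_index(build_voxel_index(m), pts, r)
      b <- fsubr:::brute_force_nearest(m, pts, r)
      expect_equal(a, b)
    }
  })
})

test_that("radial search honours the budget exactly around 3.2 mm geometry", {
  # One set voxel; endpoint placed 3.2 mm from its centre.
  m <- mask_from_voxels(cbind(5, 5, 5))
  s <- straight_streamline(c(5, 5, 0), c(5, 5, 1.8), n = 4L)  # ends 3.2 mm away
  idx <- build_voxel_index(m)
  for (r in c(2, 3)) {
    a <- match_endpoint(s, "last", idx, match_params("radial", search_dist_mm = r))
    expect_false(a$matched)
  }
  a <- match_endpoint(s, "last", idx, match_params("radial", search_dist_mm = 3.5))
  expect_true(a$matched)
  expect_equal(a$distance_mm, 3.2, tolerance = 1e-9)
})

test_that("forward search marches along the terminal tangent", {
  # Set voxel spans [7.5, 8.5] in x; streamline along +x ends at x = 6.1,
  # i.e. 1.4 mm short of the voxel's near face.
  m <- mask_from_voxels(cbind(8, 5, 5))
  s <- straight_streamline(c(3, 5, 5), c(6.1, 5, 5), n = 5L)
  idx <- build_voxel_index(m)
  p <- match_params("forward", search_dist_mm = 3, forward_step_mm = 0.5)
  a <- match_endpoint(s, "last", idx, p)
  expect_true(a$matched)
  expect_equal(a$distance_mm, 1.5)  # 3rd step of 0.5 mm
  expect_equal(a$voxel_i, 8)
  # budget too small: 2 steps reach only 6.6 < 7.5
  p2 <- match_params("forward", search_dist_mm = 1, forward_step_mm = 0.5)
  expect_false(match_endpoint(s, "last", idx, p2)$matched)
})

test_that("a degenerate terminal tangent falls back to radial with a warning", {
  m <- mask_from_voxels(cbind(5, 5, 5))
  s <- matrix(c(5, 5, 4.2, 5, 5, 4.2), ncol = 3, byrow = TRUE)
  idx <- build_voxel_index(m)
  expect_warning(
    a <- match_endpoint(s, "last", idx, match_params("forward", search_dist_mm = 2)),
    class = "fsub_warning")
  expect_true(a$matched)
  expect_equal(a$distance_mm, 0.8, tolerance = 1e-9)
})

test_that("equidistant voxels break ties to the lexicographically smallest index", {
  m <- mask_from_voxels(rbind(c(4, 5, 5), c(6, 5, 5), c(5, 4, 5), c(5, 6, 5)))
  q <- query_voxel_index(build_voxel_index(m), c(5, 5, 5), 2)
  expect_equal(c(q$voxel_i, q$voxel_j, q$voxel_k), c(4, 5, 5))
})

test_that("one-ROI extraction recovers exactly the planted bundle", {
  ph <- small_phantom(20L, 30L)
  tgt <- phantom_target_mask(ph, "A")
  res <- extract_fsub(ph$tractogram, tgt)
  expect_equal(res$selected, ph$truth$streamline[!ph$truth$is_decoy])
  rec <- evaluate_recovery(ph$truth, res)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  # assignments cover each selected streamline and stay within budget
  expect_setequal(unique(res$assignments$streamline), res$selected)
  expect_true(all(res$assignments$distance_mm <= 2))
})

test_that("two-ROI mode selects only streamlines connecting both patches", {
  ph <- make_slab_phantom(phantom_spec(
    shape = c(41L, 41L, 20L),
    patches = list(phantom_patch("A", c(-6, 0), 4), phantom_patch("B", c(7, 2), 3)),
    bundles = list(phantom_bundle("ab", "A", sink = "B", n_streamlines = 40L),
                   phantom_bundle("a_only", "A", n_streamlines = 60L)),
    n_decoys = 0L, seed = 13L))
  tA <- phantom_target_mask(ph, "A")
  tB <- phantom_target_mask(ph, "B")
  res2 <- extract_fsub(ph$tractogram, tA, roi2 = tB)
  expect_equal(res2$selected,
               ph$truth$streamline[ph$truth$bundle == "ab"])
  # two-ROI selection is a subset of each one-ROI selection
  r1 <- extract_fsub(ph$tractogram, tA)
  rB <- extract_fsub(ph$tractogram, tB)
  expect_true(all(res2$selected %in% r1$selected))
  expect_true(all(res2$selected %in% rB$selected))
  # each selected streamline has assignments to both ROIs on distinct ends
  by_sl <- split(res2$assignments, res2$assignments$streamline)
  for (tbl in by_sl) {
    expect_setequal(tbl$roi, c("roi1", "roi2"))
    expect_equal(nrow(tbl), 2L)
    expect_false(tbl$which_end[1] == tbl$which_end[2])
  }
})

test_that("endpoint search equals radial search when endpoints sit at voxel centres", {
  m <- mask_from_voxels(rbind(c(2, 2, 2), c(7, 7, 7)))
  sl <- list(straight_streamline(c(2, 2, 8), c(2, 2, 2)),
             straight_streamline(c(7, 7, 0), c(7, 7, 7)),
             straight_streamline(c(0, 0, 0), c(0, 0, 4)))
  t <- tractogram(sl)
  r_ep <- suppressWarnings(
    extract_fsub(t, m, params = match_params("endpoint", search_dist_mm = 0)))
  r_rad <- suppressWarnings(
    extract_fsub(t, m, params = match_params("radial", search_dist_mm = 0.4)))
  expect_equal(r_ep$selected, r_rad$selected)
  expect_equal(r_ep$selected, c(1L, 2L))
})

test_that("selection is monotone in the search radius", {
  ph <- small_phantom(15L, 25L, jitter = 0.8, offset = -1)
  tgt <- phantom_target_mask(ph, "A")
  radii <- c(0.5, 1, 2, 3, 4)
  for (st in c("radial", "forward")) {
    prev <- integer(0)
    for (r in radii) {
      sel <- suppressWarnings(
        extract_fsub(ph$tractogram, tgt,
                     params = match_params(st, search_dist_mm = r)))$selected
      expect_true(all(prev %in% sel))
      prev <- sel
    }
  }
})

test_that("extraction is equivariant under rigid motion of tractogram and masks", {
  ph <- small_phantom(10L, 15L)
  tgt <- phantom_target_mask(ph, "A")
  base <- extract_fsub(ph$tractogram, tgt)$selected
  for (seed in 1:5) {
    rig <- random_rigid_affine(seed)
    t2 <- apply_affine(ph$tractogram, rig)
    tgt2 <- binary_mask(tgt$values, affine_matrix(unclass(rig) %*% unclass(tgt$affine)))
    expect_equal(extract_fsub(t2, tgt2)$selected, base)
  }
})

test_that("subsetting preserves geometry and weights; FSuB is a pure subset", {
  ph <- small_phantom(8L, 5L)
  t <- ph$tractogram
  t$weights <- seq_along(t$streamlines) + 0.5
  keep <- c(2L, 5L, 9L)
  sub <- subset_tractogram(t, keep)
  expect_identical(sub$streamlines, t$streamlines[keep])
  expect_equal(sub$weights, t$weights[keep])
  expect_identical(subset_tractogram(t, seq_along(t$streamlines))$streamlines,
                   t$streamlines)
  expect_length(subset_tractogram(t, integer(0))$streamlines, 0L)
  expect_error(subset_tractogram(t, 99L), class = "fsub_validation_error")

  tgt <- phantom_target_mask(ph, "A")
  res <- extract_fsub(t, tgt)
  fsub <- subset_tractogram(t, res$selected)
  for (i in seq_along(res$selected)) {
    expect_identical(fsub$streamlines[[i]], t$streamlines[[res$selected[i]]])
  }
})

test_that("tiny extractions warn; empty inputs error", {
  ph <- small_phantom(3L, 10L)
  tgt <- phantom_target_mask(ph, "A")
  expect_warning(res <- extract_fsub(ph$tractogram, tgt),
                 class = "fsub_small_fsub_warning")
  expect_length(res$selected, 3L)
  expect_error(extract_fsub(ph$tractogram,
                            binary_mask(array(0, dim(tgt$values)), tgt$affine)),
               class = "fsub_validation_error")
  expect_error(extract_fsub(subset_tractogram(ph$tractogram, integer(0)), tgt),
               class = "fsub_validation_error")
})
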