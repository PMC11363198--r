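# Shared fixtures, all built in code at test time.

# Small one-ROI phantom: one free-ended bundle into patch A plus decoys.
small_phantom <- function(n_target = 20L, n_decoys = 30L, seed = 7L,
                          jitter = 0, offset = 0) {
  make_slab_phantom(phantom_spec(
    shape = c(41L, 41L, 20L),
    patches = list(phantom_patch("A", c(-6, 0), 4, peak = 10),
                   phantom_patch("B", c(7, 2), 3, peak = 8)),
    bundles = list(phantom_bundle("target", "A", n_streamlines = n_target,
                                  endpoint_offset_mm = offset,
                                  jitter_sd_mm = jitter)),
    n_decoys = n_decoys, seed = seed))
}

# fROI-x-GMWMI target mask for a phantom patch.
phantom_target_mask <- function(ph, patch = "A", gmwmi_threshold = 0.25) {
  gm <- binarize(compute_gmwmi(ph$seg), gmwmi_threshold)
  proj <- project_label_to_volume(ph$mesh, ph$labels[[patch]], ph$grid)
  suppressWarnings(intersect_masks(proj, gm))
}

# A tiny deterministic mask: given 0-based voxel indices on a grid.
mask_from_voxels <- function(ijk, dim = c(10L, 10L, 10L), affine = diag(4)) {
  arr <- array(0, dim = dim)
  for (r in seq_len(nrow(ijk))) {
    arr[ijk[r, 1] + 1L, ijk[r, 2] + 1L, ijk[r, 3] + 1L] <- 1
  }
  binary_mask(arr, affine)
}

# Straight-line streamline between two points with n samples.
straight_streamline <- function(p0, p1, n = 5L) {
  tt <- seq(0, 1, length.out = n)
  outer(1 - tt, p0) + outer(tt, p1)
}

# Random rigid transform (rotation + translation) from a seed.
random_rigid_affine <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    m <- diag(4)
    m[1:3, 1:3] <- q
    m[1:3, 4] <- stats::runif(3, -10, 10)
    affine_matrix(m)
  })
}

expect_tractograms_equal <- function(a, b, tol = 1e-4) {
  expect_equal(length(a$streamlines), length(b$streamlines))
  if (length(a$streamlines)) {
    err <- max(mapply(function(x, y) max(abs(x - y)), a$streamlines, b$streamlines))
    expect_lt(err, tol)
  }
}
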