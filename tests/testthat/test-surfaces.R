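# Vertex normals, volume sampling, label projection, percentile thresholding.

flat_grid_mesh <- function(n = 5L) {
  gv <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L))
  v <- cbind(gv$x, gv$y, 0)
  vid <- function(i, j) (j - 1L) * n + i
  faces <- do.call(rbind, lapply(seq_len(n - 1L), function(j) {
    do.call(rbind, lapply(seq_len(n - 1L), function(i) {
      rbind(c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
            c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
    }))
  }))
  surface_mesh(v, faces, space_tag = "world")
}

unit_sphere_mesh <- function(n_theta = 16L, n_phi = 32L) {
  th <- seq(0.15, pi - 0.15, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(t = th, p = ph)
  v <- cbind(sin(g$t) * cos(g$p), sin(g$t) * sin(g$p), cos(g$t))
  vid <- function(i, j) (j - 1L) * n_theta + i
  faces <- do.call(rbind, lapply(seq_len(n_phi), function(j) {
    jn <- if (j == n_phi) 1L else j + 1L
    do.call(rbind, lapply(seq_len(n_theta - 1L), function(i) {
      rbind(c(vid(i, j), vid(i + 1L, jn), vid(i, jn)),
            c(vid(i, j), vid(i + 1L, j), vid(i + 1L, jn)))
    }))
  }))
  surface_mesh(v, faces, space_tag = "world")
}

test_that("normals of a flat CCW grid all point +z and are unit length", {
  mesh <- flat_grid_mesh()
  n <- compute_vertex_normals(mesh)
  expect_equal(n, matrix(rep(c(0, 0, 1), each = nrow(n)), ncol = 3))
  expect_equal(row_norms <- sqrt(rowSums(n^2)), rep(1, nrow(n)), tolerance = 1e-6)
})

test_that("sphere normals are radial within 5 degrees", {
  n_theta <- 16L
  mesh <- unit_sphere_mesh(n_theta = n_theta)
  n <- compute_vertex_normals(mesh)
  cosang <- rowSums(n * mesh$vertices) / sqrt(rowSums(mesh$vertices^2))
  # interior vertices only: the open polar rims have one-sided face fans
  interior <- rep(seq_len(n_theta), times = nrow(mesh$vertices) / n_theta)
  interior <- interior > 1L & interior < n_theta
  expect_true(all(acos(pmin(1, cosang[interior])) < 5 * pi / 180))
})

test_that("a single triangle gives the face normal at all three vertices", {
  mesh <- surface_mesh(matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0), ncol = 3, byrow = TRUE),
                       matrix(c(1, 2, 3), ncol = 3))
  n <- compute_vertex_normals(mesh)
  expect_equal(n, matrix(rep(c(0, 0, 1), each = 3), ncol = 3))
})

test_that("isolated vertices get zero normals with a warning", {
  mesh <- surface_mesh(rbind(diag(3), c(5, 5, 5)), matrix(c(1, 2, 3), ncol = 3))
  expect_warning(n <- compute_vertex_normals(mesh), class = "fsub_warning")
  expect_equal(n[4, ], c(0, 0, 0))
})

test_that("sampling a constant volume returns the constant everywhere", {
  mesh <- flat_grid_mesh()
  vol <- volume_image(array(7, dim = c(10, 10, 10)),
                      {a <- diag(4); a[3, 4] <- -5; a})
  s <- sample_volume_at_vertices(vol, mesh, projection_params(2, 0.5))
  expect_equal(s$values, rep(7, nrow(mesh$vertices)))
  expect_false(any(s$missing))
})

test_that("trilinear sampling of a linear ramp is exact at depth 0", {
  dims <- c(8, 8, 8)
  zval <- array(rep(0:7, each = 64), dim = dims)
  vol <- volume_image(zval, diag(4))
  mesh <- surface_mesh(matrix(c(3, 3, 1.25, 4, 3, 1.25, 3, 4, 1.25),
                              ncol = 3, byrow = TRUE),
                       matrix(c(1, 2, 3), ncol = 3))
  s <- sample_volume_at_vertices(vol, mesh, projection_params(0, 0.25),
                                 interp = "trilinear")
  expect_equal(s$values, rep(1.25, 3), tolerance = 1e-12)
})

test_that("vertices fully outside the grid sample 0 and are flagged missing", {
  vol <- volume_image(array(5, dim = c(4, 4, 4)), diag(4))
  mesh <- surface_mesh(matrix(c(1, 1, 1, 50, 50, 50, 2, 1, 1),
                              ncol = 3, byrow = TRUE),
                       matrix(c(1, 2, 3), ncol = 3))
  s <- sample_volume_at_vertices(vol, mesh, projection_params(0, 0.25))
  expect_equal(s$values[2], 0)
  expect_true(s$missing[2])
  expect_false(s$missing[1])
})

test_that("an entirely out-of-grid mesh raises a space-mismatch error", {
  vol <- volume_image(array(1, dim = c(4, 4, 4)), diag(4))
  mesh <- flat_grid_mesh()
  mesh$vertices <- mesh$vertices + 1000
  expect_error(sample_volume_at_vertices(vol, mesh), class = "fsub_space_error")
})

test_that("projection with depth 0 of a vertex at a voxel centre sets that voxel", {
  grid <- volume_image(array(0, dim = c(9, 9, 9)),
                       {a <- diag(4); a[1:3, 4] <- -4; a})
  mesh <- flat_grid_mesh()
  lab <- vertex_label(1L)  # vertex (0, 0, 0) = voxel (4, 4, 4)
  m <- project_label_to_volume(mesh, lab, grid, projection_params(0, 0.25))
  expect_equal(sum(m$values), 1)
  expect_equal(which(m$values == 1), 4 + 9 * 4 + 81 * 4 + 1)
})

test_that("disc projection matches a brute-force point-in-cylinder oracle up to the boundary shell", {
  ph <- small_phantom(0L, 0L)
  params <- projection_params(2, 0.25)
  m <- project_label_to_volume(ph$mesh, ph$labels$A, ph$grid, params)
  # Oracle: voxel centres within the swept cylinder (disc radius 4 under
  # patch A, z in [-2, 0]), allowing a one-voxel boundary shell.
  ctr <- ph$spec$patches[[1]]$center
  radius <- ph$spec$patches[[1]]$radius_mm
  dm <- dim(ph$grid$values)
  idx <- arrayInd(seq_along(ph$grid$values), dm) - 1L
  world <- voxel_centers_mm(ph$grid, idx)
  d2 <- sqrt((world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2)
  inz <- world[, 3] >= -2 & world[, 3] <= 0
  inner <- d2 <= radius - 1 & world[, 3] >= -1.5 & world[, 3] <= -0.5
  outer_shell <- d2 <= radius + 1 & world[, 3] >= -3 & world[, 3] <= 1
  got <- m$values[cbind(idx[, 1] + 1, idx[, 2] + 1, idx[, 3] + 1)] == 1
  expect_true(all(got[inner]))          # everything comfortably inside is set
  expect_true(all(!got[!outer_shell]))  # nothing beyond the boundary shell
})

test_that("two distant patches project to two 6-connected components", {
  ph <- small_phantom(0L, 0L)
  both <- vertex_label(c(ph$labels$A$vertex_indices, ph$labels$B$vertex_indices))
  m <- project_label_to_volume(ph$mesh, both, ph$grid, projection_params(1, 0.25))
  # 6-connectivity component count by flood fill.
  dm <- dim(m$values)
  seen <- array(FALSE, dm)
  comps <- 0L
  set <- which(m$values == 1)
  for (s in set) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (seen[cur]) next
      seen[cur] <- TRUE
      ijk <- arrayInd(cur, dm)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- ijk; nb[ax] <- nb[ax] + dd
        if (nb[ax] >= 1L && nb[ax] <= dm[ax]) {
          lin <- nb[1] + dm[1] * (nb[2] - 1L) + dm[1] * dm[2] * (nb[3] - 1L)
          if (m$values[lin] == 1 && !seen[lin]) queue <- c(queue, lin)
        }
      }
    }
  }
  expect_equal(comps, 2L)
})

test_that("projected voxel count is monotone in depth and empty labels error", {
  ph <- small_phantom(0L, 0L)
  counts <- vapply(c(0, 1, 2, 3), function(d) {
    sum(project_label_to_volume(ph$mesh, ph$labels$A, ph$grid,
                                projection_params(d, 0.25))$values)
  }, double(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(project_label_to_volume(ph$mesh, vertex_label(integer(0)), ph$grid),
               class = "fsub_validation_error")
})

test_that("nearest-rank percentile thresholding selects the strict top tail", {
  space <- vertex_label(1:100)
  sel <- threshold_percentile(1:100, space, 90)
  expect_equal(sort(sel$vertex_indices), 91:100)
  expect_length(sel, 10L)

  # percentile 0 selects everything strictly above the minimum
  sel0 <- threshold_percentile(1:100, space, 0)
  expect_equal(sort(sel0$vertex_indices), 2:100)

  expect_warning(empty <- threshold_percentile(rep(3, 100), space, 90),
                 class = "fsub_warning")
  expect_length(empty, 0L)
  expect_error(threshold_percentile(1:100, space, 100),
               class = "fsub_parameter_error")
})

test_that("percentile selection is permutation-invariant and bounded", {
  withr::with_seed(11, {
    vals <- stats::rnorm(137)
    for (p in c(25, 50, 90)) {
      space <- vertex_label(1:137)
      sel <- threshold_percentile(vals, space, p)
      perm <- sample(137)
      sel2 <- threshold_percentile(vals, vertex_label(perm), p)
      expect_setequal(sel$vertex_indices, sel2$vertex_indices)
      expect_lte(length(sel), ceiling((100 - p) / 100 * 137))
    }
  })
})

test_that("rigid transforms preserve pairwise distances; inverse undoes", {
  pts <- withr::with_seed(5, matrix(stats::rnorm(60), ncol = 3))
  aff <- random_rigid_affine(9)
  moved <- apply_affine(pts, aff)
  expect_equal(as.vector(stats::dist(moved)), as.vector(stats::dist(pts)),
               tolerance = 1e-9)
  back <- apply_affine(moved, affine_inverse(aff))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("max-combine sampling is monotone in the volume", {
  mesh <- flat_grid_mesh()
  a <- diag(4); a[3, 4] <- -5
  base <- withr::with_seed(2, array(stats::runif(1000), dim = c(10, 10, 10)))
  v1 <- volume_image(base, a)
  v2 <- volume_image(base + 0.3, a)
  s1 <- sample_volume_at_vertices(v1, mesh, projection_params(2, 0.5))
  s2 <- sample_volume_at_vertices(v2, mesh, projection_params(2, 0.5))
  expect_true(all(s2$values >= s1$values))
})
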