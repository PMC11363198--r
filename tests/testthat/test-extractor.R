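# End-to-end workflow: orchestration, naming, determinism, snapshots.

extractor_fixture <- function(dir, two_roi = FALSE, n_target = 20L,
                              n_decoys = 30L, seed = 7L) {
  ph <- if (two_roi) {
    make_slab_phantom(phantom_spec(
      shape = c(41L, 41L, 20L),
      patches = list(phantom_patch("A", c(-6, 0), 4), phantom_patch("B", c(7, 2), 3)),
      bundles = list(phantom_bundle("ab", "A", sink = "B", n_streamlines = 40L),
                     phantom_bundle("a_only", "A", n_streamlines = 60L)),
      n_decoys = 0L, seed = seed))
  } else {
    small_phantom(n_target, n_decoys, seed = seed)
  }
  manifest <- write_phantom_dataset(ph, dir)
  list(ph = ph, files = manifest)
}

fixture_config <- function(fx, dir, out_dir, two_roi = FALSE, ...) {
  path_for <- function(role, pattern = NULL) {
    p <- fx$files$path[fx$files$role == role]
    if (!is.null(pattern)) p <- p[grepl(pattern, p)]
    p[1]
  }
  run_config(
    subject = "phantom01",
    tract = path_for("tractogram"),
    tract_name = "combined",
    roi1 = path_for("label", "desc-A"), roi1_name = "patchA",
    roi2 = if (two_roi) path_for("label", "desc-B") else NULL,
    roi2_name = if (two_roi) "patchB" else NULL,
    surface = path_for("surface"),
    fivett = path_for("5tt"),
    out_dir = out_dir, ...)
}

test_that("a one-ROI run recovers the ground-truth count and writes a manifest", {
  dir <- withr::local_tempdir()
  fx <- extractor_fixture(dir)
  out <- file.path(dir, "out")
  run <- run_extractor(fixture_config(fx, dir, out))
  truth_n <- sum(!fx$ph$truth$is_decoy)
  expect_equal(length(run$result$selected), truth_n)
  expect_equal(length(run$fsub$streamlines), truth_n)
  expect_true(all(file.exists(run$manifest$path)))
  expect_setequal(
    c("gmwmi_probability", "gmwmi_mask", "froi_mask",
      "froi_gmwmi_intersection", "fsub_tractogram", "assignments",
      "summary", "snapshot", "snapshot_legend", "log"),
    unique(run$manifest$role))
  fsub_path <- run$manifest$path[run$manifest$role == "fsub_tractogram"]
  expect_length(read_tck(fsub_path)$streamlines, truth_n)
})

test_that("a two-ROI run keeps only streamlines connecting both fROIs", {
  dir <- withr::local_tempdir()
  fx <- extractor_fixture(dir, two_roi = TRUE)
  out <- file.path(dir, "out")
  run <- run_extractor(fixture_config(fx, dir, out, two_roi = TRUE))
  expect_equal(length(run$result$selected),
               sum(fx$ph$truth$bundle == "ab"))
})

test_that("reruns with an identical config produce byte-identical outputs", {
  dir <- withr::local_tempdir()
  fx <- extractor_fixture(dir)
  run1 <- run_extractor(fixture_config(fx, dir, file.path(dir, "o1")))
  run2 <- run_extractor(fixture_config(fx, dir, file.path(dir, "o2")))
  for (k in seq_len(nrow(run1$manifest))) {
    p1 <- run1$manifest$path[k]
    p2 <- run2$manifest$path[k]
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)),
                     label = basename(p1))
  }
})

test_that("output names parse back into their generating parameters", {
  nm <- "sub-phantom01_desc-combined_roi-patchA_roi-patchB_fsub.tck"
  p <- parse_output_name(nm)
  expect_equal(p$subject, "phantom01")
  expect_equal(p$tract_name, "combined")
  expect_equal(p$roi_names, c("patchA", "patchB"))
  expect_equal(p$suffix, "fsub.tck")
  expect_null(parse_output_name("unrelated.txt"))
})

test_that("snapshots exist with declared dimensions and legend colors", {
  dir <- withr::local_tempdir()
  ph <- small_phantom(10L, 5L)
  tgt <- phantom_target_mask(ph, "A")
  res <- extract_fsub(ph$tractogram, tgt)
  fsub <- subset_tractogram(ph$tractogram, res$selected)
  p <- file.path(dir, "snap.png")
  colors <- list(bundle = "#112233", fsub = "#AABBCC", roi = "#445566")
  meta <- render_snapshot(ph$tractogram, fsub, tgt, p, colors = colors)
  expect_true(file.exists(p) && file.size(p) > 0)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(meta$height, meta$width))
  legend <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(unlist(legend$colors), unlist(colors))
  expect_false(legend$warning_banner)
})

test_that("FSuB equal to the whole tract covers identical overlay pixel sets", {
  dir <- withr::local_tempdir()
  ph <- small_phantom(8L, 0L)
  tgt <- phantom_target_mask(ph, "A")
  p <- file.path(dir, "snap.png")
  meta <- render_snapshot(ph$tractogram, ph$tractogram, tgt, p)
  for (panel in meta$pixel_sets) {
    expect_identical(panel$bundle, panel$fsub)
  }
})

test_that("an empty FSuB still renders, with a warning banner", {
  dir <- withr::local_tempdir()
  ph <- small_phantom(5L, 0L)
  tgt <- phantom_target_mask(ph, "A")
  empty <- subset_tractogram(ph$tractogram, integer(0))
  p <- file.path(dir, "snap.png")
  meta <- render_snapshot(ph$tractogram, empty, tgt, p)
  expect_true(file.exists(p))
  expect_true(meta$warning_banner)
})

test_that("invalid configurations are rejected up front", {
  expect_error(run_config(subject = "s", tract = "missing.tck",
                          tract_name = "t", roi1 = "missing.label",
                          roi1_name = "r"),
               class = "fsub_io_error")
  dir <- withr::local_tempdir()
  fx <- extractor_fixture(dir, n_target = 2L, n_decoys = 2L)
  tract <- fx$files$path[fx$files$role == "tractogram"]
  roi <- fx$files$path[fx$files$role == "label"][1]
  surf <- fx$files$path[fx$files$role == "surface"]
  expect_error(run_config(subject = "s", tract = tract, tract_name = "t",
                          roi1 = roi, roi1_name = "r", surface = surf),
               class = "fsub_parameter_error")  # no 5tt and no GMWMI
})
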