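#' Extraction run configuration
#'
#' Validates paths and parameters for a full extraction run. fROIs may be
#' FreeSurfer `.label` files (projected into the interface along vertex
#' normals, which requires `surface`) or NIfTI binary masks (used on their
#' grid directly). A 5tt image or a precomputed GMWMI probability image must
#' be supplied; when both are given the precomputed GMWMI wins (and this is
#' logged).
#'
#' @param subject Subject identifier used in output names.
#' @param tract Path to the input tractogram (`.tck` or `.trk`).
#' @param tract_name Descriptive tract name for output files.
#' @param roi1,roi2 fROI paths (`.label` or NIfTI); `roi2` optional.
#' @param roi1_name,roi2_name Descriptive ROI names.
#' @param hemisphere `"lh"` or `"rh"`.
#' @param surface Path to a FreeSurfer binary surface (required for `.label`
#'   fROIs).
#' @param fs2dwi Optional path to a 4x4 affine text file taking surface
#'   space into the tractogram/DWI space.
#' @param fivett Optional path to a 4-D 5tt NIfTI image.
#' @param gmwmi Optional path to a precomputed GMWMI probability NIfTI.
#' @param weights Optional path to a per-streamline weights text file.
#' @param gmwmi_threshold Binarization threshold for the GMWMI.
#' @param match A [match_params()].
#' @param projection A [projection_params()].
#' @param out_dir Output directory.
#' @param colors Named list of snapshot colors (`bundle`, `fsub`, `roi`).
#' @return A validated `fsub_run_config` list.
#' @export
run_config <- function(subject, tract, tract_name, roi1, roi1_name,
                       roi2 = NULL, roi2_name = NULL,
                       hemisphere = c("lh", "rh"), surface = NULL,
                       fs2dwi = NULL, fivett = NULL, gmwmi = NULL,
                       weights = NULL, gmwmi_threshold = 0.25,
                       match = match_params(), projection = projection_params(),
                       out_dir = ".",
                       colors = list(bundle = "#D55E00", fsub = "#FFFFFF",
                                     roi = "#0072B2")) {
  hemisphere <- match.arg(hemisphere)
  if (is.null(roi2) != is.null(roi2_name)) {
    abort_parameter("roi2 and roi2_name must be supplied together")
  }
  for (p in c(tract, roi1, roi2, surface, fs2dwi, fivett, gmwmi, weights)) {
    stopifnot_file_exists(p, "input")
  }
  needs_surface <- any(grepl("\\.label$", c(roi1, roi2)))
  if (needs_surface && is.null(surface)) {
    abort_parameter(".label fROIs require a surface")
  }
  if (is.null(fivett) && is.null(gmwmi)) {
    abort_parameter("supply a 5tt image or a precomputed GMWMI")
  }
  structure(list(subject = subject, tract = tract, tract_name = tract_name,
                 roi1 = roi1, roi1_name = roi1_name,
                 roi2 = roi2, roi2_name = roi2_name,
                 hemisphere = hemisphere, surface = surface, fs2dwi = fs2dwi,
                 fivett = fivett, gmwmi = gmwmi, weights = weights,
                 gmwmi_threshold = gmwmi_threshold, match = match,
                 projection = projection, out_dir = out_dir, colors = colors),
            class = "fsub_run_config")
}

# BIDS-like output naming: sub-<id>_desc-<tract>_roi-<roi1>[_roi-<roi2>]_<suffix>.
# Not a claim of BIDS compliance; the scheme is versioned and parseable.
fsub_output_name <- function(cfg, suffix) {
  roi_part <- sprintf("_roi-%s", cfg$roi1_name)
  if (!is.null(cfg$roi2_name)) {
    roi_part <- paste0(roi_part, sprintf("_roi-%s", cfg$roi2_name))
  }
  sprintf("sub-%s_desc-%s%s_%s", cfg$subject, cfg$tract_name, roi_part, suffix)
}

#' Parse an output file name back into its generating fields
#'
#' @param filename A file name produced by [run_extractor()].
#' @return A list with `subject`, `tract_name`, `roi_names`, `suffix`, or
#'   `NULL` if the name does not follow the scheme.
#' @export
parse_output_name <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base, regexec(
    "^sub-([^_]+)_desc-([^_]+)((?:_roi-[^_]+)+)_(.+)$", base))[[1]]
  if (length(m) == 0L) return(NULL)
  rois <- regmatches(m[4], gregexpr("_roi-([^_]+)", m[4]))[[1]]
  list(subject = m[2], tract_name = m[3],
       roi_names = sub("^_roi-", "", rois), suffix = m[5])
}

load_froi <- function(path, cfg, grid, log) {
  if (grepl("\\.label$", path)) {
    mesh <- read_fs_surface(cfg$surface)
    mesh <- surface_to_world(mesh)
    if (!is.null(cfg$fs2dwi)) {
      mesh <- apply_affine(mesh, read_affine_text(cfg$fs2dwi))
      log("applied fs2dwi affine to surface")
    }
    label <- read_label(path, hemisphere = cfg$hemisphere)
    project_label_to_volume(mesh, label, grid, cfg$projection)
  } else {
    v <- read_volume(path)
    binary_mask((v$values != 0) * 1, v$affine)
  }
}

#' Run the full extraction workflow
#'
#' Executes, in order: load inputs; apply the surface-to-DWI affine to
#' surface-derived objects when supplied; compute (or load) and binarize the
#' GMWMI; project the fROI(s); intersect each fROI with the interface;
#' convert the tractogram to the internal world-mm representation; match
#' endpoints and extract the FSuB; and write the FSuB tractogram,
#' assignments table, JSON summary, snapshot image, and all intermediates
#' under BIDS-like names. The run is a pure function of the input files and
#' configuration.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `result` (the `fsub_result`), `fsub`
#'   (tractogram), `summary` (tibble), and `manifest` (tibble of every
#'   output file with a role tag).
#' @export
run_extractor <- function(cfg) {
  if (!inherits(cfg, "fsub_run_config")) abort_validation("cfg must be a run_config()")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) log_lines <<- c(log_lines, sprintf(...))
  files <- character(0); roles <- character(0); flags <- character(0)
  emit <- function(path, role, flag = "complete") {
    files <<- c(files, path); roles <<- c(roles, role); flags <<- c(flags, flag)
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("step '%s' failed: %s", name, conditionMessage(e)),
                   class = c("fsub_step_error", class(e)), parent = e)
    })
  }
  out <- function(suffix) file.path(cfg$out_dir, fsub_output_name(cfg, suffix))

  log("subject: %s", cfg$subject)
  log("tract: %s (%s)", cfg$tract, cfg$tract_name)
  log("search_type: %s; search_dist_mm: %g; forward_step_mm: %g",
      cfg$match$search_type, cfg$match$search_dist_mm, cfg$match$forward_step_mm)
  log("gmwmi_threshold: %g", cfg$gmwmi_threshold)
  log("projection: depth %g mm, step %g mm, combine %s",
      cfg$projection$inward_depth_mm, cfg$projection$step_mm,
      cfg$projection$combine)

  tract <- step("load tractogram", {
    if (grepl("\\.trk$", cfg$tract)) read_trk(cfg$tract) else read_tck(cfg$tract)
  })
  log("loaded %d streamlines (%s)", length(tract$streamlines),
      tract$meta$format)
  if (!is.null(cfg$weights)) {
    tract$weights <- step("load weights",
      read_streamline_weights(cfg$weights, length(tract$streamlines)))
  }

  gmwmi_prob <- step("GMWMI", {
    if (!is.null(cfg$gmwmi)) {
      if (!is.null(cfg$fivett)) {
        log("both 5tt and precomputed GMWMI supplied; using the precomputed GMWMI")
      }
      read_volume(cfg$gmwmi)
    } else {
      compute_gmwmi(read_5tt(cfg$fivett))
    }
  })
  p <- out("gmwmiprob.nii"); write_volume(gmwmi_prob, p); emit(p, "gmwmi_probability")
  gmwmi_mask <- step("binarize GMWMI", binarize(gmwmi_prob, cfg$gmwmi_threshold))
  p <- out("gmwmimask.nii"); write_volume(gmwmi_mask, p); emit(p, "gmwmi_mask")

  targets <- list()
  roi_paths <- c(cfg$roi1, cfg$roi2)
  roi_names <- c(cfg$roi1_name, cfg$roi2_name)
  for (k in seq_along(roi_paths)) {
    proj <- step(sprintf("project fROI %s", roi_names[k]),
                 load_froi(roi_paths[k], cfg, gmwmi_prob, log))
    p <- out(sprintf("space-dwi_desc-%s_mask.nii", roi_names[k]))
    write_volume(proj, p); emit(p, "froi_mask")
    tgt <- step(sprintf("intersect fROI %s with GMWMI", roi_names[k]),
                suppressWarnings(intersect_masks(proj, gmwmi_mask)))
    p <- out(sprintf("space-dwi_desc-%sxgmwmi_mask.nii", roi_names[k]))
    write_volume(tgt, p); emit(p, "froi_gmwmi_intersection")
    targets[[k]] <- tgt
  }

  result <- step("match and extract", withCallingHandlers(
    extract_fsub(tract, targets[[1]],
                 roi2 = if (length(targets) > 1L) targets[[2]] else NULL,
                 params = cfg$match, roi_names = roi_names),
    fsub_warning = function(w) {
      log("warning: %s", conditionMessage(w))
      rlang::cnd_muffle(w)
    }))
  log("selected %d of %d streamlines", length(result$selected), result$n_input)
  fsub <- subset_tractogram(tract, result$selected)

  p <- out("fsub.tck")
  if (length(fsub$streamlines) > 0L) {
    write_tck(fsub, p); emit(p, "fsub_tractogram")
  } else {
    write_tck(fsub, p); emit(p, "fsub_tractogram", flag = "empty")
  }
  p <- out("assignments.tsv")
  utils::write.table(result$assignments, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  emit(p, "assignments")

  summary_tbl <- fsub_summary(result, fsub, targets[[1]])
  p <- out("summary.json")
  jsonlite::write_json(list(
    subject = cfg$subject, tract_name = cfg$tract_name, roi_names = roi_names,
    params = list(search_type = cfg$match$search_type,
                  search_dist_mm = cfg$match$search_dist_mm,
                  forward_step_mm = cfg$match$forward_step_mm,
                  gmwmi_threshold = cfg$gmwmi_threshold,
                  inward_depth_mm = cfg$projection$inward_depth_mm,
                  step_mm = cfg$projection$step_mm),
    n_input = result$n_input, n_selected = length(result$selected),
    summary = as.list(summary_tbl), warnings = result$warnings),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(p, "summary")

  p <- out("snapshot.png")
  snap <- step("snapshot", render_snapshot(tract, fsub, targets, p,
                                           colors = cfg$colors))
  emit(p, "snapshot")
  emit(paste0(p, ".json"), "snapshot_legend")

  p <- out("log.txt")
  writeLines(log_lines, p); emit(p, "log")
  manifest <- tibble::tibble(path = files, role = roles, status = flags)
  p <- out("manifest.tsv")
  utils::write.table(manifest, p, sep = "\t", row.names = FALSE, quote = FALSE)

  invisible(list(result = result, fsub = fsub, summary = summary_tbl,
                 manifest = manifest, snapshot = snap, log = log_lines))
}
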