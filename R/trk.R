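# TrackVis TRK v2: 1000-byte header, then per streamline an int32 point
# count, the points as float32 (x, y, z, scalars...), and per-streamline
# property floats. Points are stored in "voxel-mm" with a corner origin:
# stored coordinate p corresponds to voxel index p / voxel_size - 0.5, which
# is then mapped through the header's voxel-to-RAS matrix to world mm.

TRK_HDR_SIZE <- 1000L

read_trk_header <- function(con, path) {
  raw_hdr <- readBin(con, "raw", n = TRK_HDR_SIZE)
  if (length(raw_hdr) < TRK_HDR_SIZE) {
    abort_format(sprintf("TRK file shorter than its 1000-byte header: %s", path))
  }
  hdr_size_at <- function(endian) {
    readBin(raw_hdr[997:1000], "integer", size = 4L, endian = endian)
  }
  endian <- if (hdr_size_at("little") == TRK_HDR_SIZE) {
    "little"
  } else if (hdr_size_at("big") == TRK_HDR_SIZE) {
    "big"
  } else {
    abort_format(sprintf("TRK hdr_size is not 1000 under either byte order: %s", path))
  }
  rd_i16 <- function(off, n = 1L) readBin(raw_hdr[(off + 1L):(off + 2L * n)],
                                          "integer", n = n, size = 2L, endian = endian)
  rd_i32 <- function(off, n = 1L) readBin(raw_hdr[(off + 1L):(off + 4L * n)],
                                          "integer", n = n, size = 4L, endian = endian)
  rd_f32 <- function(off, n = 1L) readBin(raw_hdr[(off + 1L):(off + 4L * n)],
                                          "numeric", n = n, size = 4L, endian = endian)
  magic <- rawToChar(raw_hdr[1:5])
  if (!identical(magic, "TRACK")) {
    abort_format(sprintf("not a TRK file (missing TRACK magic): %s", path))
  }
  list(
    endian = endian,
    dim = rd_i16(6L, 3L),
    voxel_size = rd_f32(12L, 3L),
    n_scalars = rd_i16(36L),
    n_properties = rd_i16(238L),
    vox_to_ras = matrix(rd_f32(440L, 16L), 4L, 4L, byrow = TRUE),
    voxel_order = rawToChar(raw_hdr[949:952][raw_hdr[949:952] != as.raw(0)]),
    n_count = rd_i32(988L),
    version = rd_i32(992L)
  )
}

# Axis codes ("R"/"A"/"S"-style triple) of a voxel-to-world affine: for each
# voxel axis, the world axis it most increases along.
affine_axcodes <- function(m) {
  lab <- c("R", "A", "S"); neg <- c("L", "P", "I")
  vapply(1:3, function(j) {
    col <- m[1:3, j]
    ax <- which.max(abs(col))
    if (col[ax] >= 0) lab[ax] else neg[ax]
  }, character(1))
}

#' Read a TrackVis TRK tractogram
#'
#' Streamline coordinates are converted from TRK's corner-origin voxel-mm
#' convention to world RAS mm using the header's voxel sizes and
#' voxel-to-RAS matrix. Per-point scalars and per-streamline properties, if
#' present, are retained as opaque metadata.
#'
#' @param path Path to a `.trk` file.
#' @return A [tractogram()] in world RAS mm.
#' @export
read_trk <- function(path) {
  stopifnot_file_exists(path, "TRK file")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_trk_header(con, path)
  M <- hdr$vox_to_ras
  if (all(M == 0) || M[4, 4] == 0) {
    abort_format(paste0(
      "TRK header carries no voxel-to-RAS matrix; re-export the tractogram ",
      "with a reference volume affine (TRK v1 files lack one): ", path))
  }
  if (nzchar(hdr$voxel_order)) {
    codes <- paste(affine_axcodes(M), collapse = "")
    if (!identical(toupper(hdr$voxel_order), codes)) {
      abort_dialect(sprintf(
        "TRK voxel_order '%s' disagrees with the affine's axis codes '%s'; reorienting exotic voxel orders is not supported",
        hdr$voxel_order, codes))
    }
  }
  ns <- hdr$n_scalars
  np <- hdr$n_properties
  streamlines <- list()
  scalars <- list()
  properties <- list()
  repeat {
    n_pts <- readBin(con, "integer", n = 1L, size = 4L, endian = hdr$endian)
    if (length(n_pts) == 0L) break
    if (n_pts <= 0L) abort_corrupt(sprintf("TRK streamline with %d points", n_pts))
    vals <- readBin(con, "numeric", n = n_pts * (3L + ns), size = 4L,
                    endian = hdr$endian)
    if (length(vals) < n_pts * (3L + ns)) {
      abort_corrupt(sprintf("TRK data truncated at byte %d", seek(con)))
    }
    m <- matrix(vals, ncol = 3L + ns, byrow = TRUE)
    pts <- m[, 1:3, drop = FALSE]
    vox <- sweep(pts, 2L, hdr$voxel_size, "/") - 0.5
    streamlines[[length(streamlines) + 1L]] <- affine_apply_points(affine_matrix(M), vox)
    if (ns > 0L) scalars[[length(scalars) + 1L]] <- m[, -(1:3), drop = FALSE]
    if (np > 0L) {
      pr <- readBin(con, "numeric", n = np, size = 4L, endian = hdr$endian)
      if (length(pr) < np) abort_corrupt(sprintf("TRK data truncated at byte %d", seek(con)))
      properties[[length(properties) + 1L]] <- pr
    }
  }
  if (hdr$n_count > 0L && hdr$n_count != length(streamlines)) {
    abort_corrupt(sprintf("TRK header declares %d streamlines but %d parsed",
                          hdr$n_count, length(streamlines)))
  }
  out <- tractogram(streamlines)
  out$meta <- list(format = "trk", path = path,
                   voxel_size = hdr$voxel_size, vox_to_ras = M,
                   voxel_order = hdr$voxel_order,
                   scalars = if (ns > 0L) scalars else NULL,
                   properties = if (np > 0L) properties else NULL)
  out
}

#' Write a TrackVis TRK tractogram
#'
#' World-mm streamlines are converted into TRK's corner-origin voxel-mm
#' convention relative to the supplied reference grid (defaults to identity
#' voxel-to-RAS with 1 mm voxels).
#'
#' @param t A [tractogram()] in world RAS mm.
#' @param path Output path.
#' @param reference Optional [volume_image()] supplying the voxel grid
#'   (dimensions and voxel-to-RAS affine) recorded in the header.
#' @return The path, invisibly.
#' @export
write_trk <- function(t, path, reference = NULL) {
  if (!inherits(t, "fsub_tractogram")) abort_validation("write_trk needs a tractogram")
  if (is.null(reference)) {
    M <- diag(4)
    dims <- c(1L, 1L, 1L)
  } else {
    M <- unclass(reference$affine)
    dims <- dim(reference$values)
  }
  voxel_size <- sqrt(colSums(M[1:3, 1:3]^2))
  inv <- solve(M)
  con <- file(path, "wb")
  on.exit(close(con))
  wr_raw <- function(n) writeBin(raw(n), con)
  writeChar("TRACK", con, eos = NULL); wr_raw(1L)               # id_string[6]
  writeBin(as.integer(dims), con, size = 2L, endian = "little") # dim[3]
  writeBin(as.double(voxel_size), con, size = 4L, endian = "little")
  writeBin(rep(0, 3), con, size = 4L, endian = "little")        # origin
  writeBin(0L, con, size = 2L, endian = "little")               # n_scalars
  wr_raw(200L)                                                  # scalar names
  writeBin(0L, con, size = 2L, endian = "little")               # n_properties
  wr_raw(200L)                                                  # property names
  writeBin(as.double(t(M)), con, size = 4L, endian = "little")  # vox_to_ras
  wr_raw(444L)                                                  # reserved
  ax <- paste(affine_axcodes(M), collapse = "")
  writeBin(c(charToRaw(ax), raw(4L - nchar(ax))), con)          # voxel_order
  wr_raw(4L)                                                    # pad2
  writeBin(rep(0, 6), con, size = 4L, endian = "little")        # image_orientation
  wr_raw(2L)                                                    # pad1
  wr_raw(6L)                                                    # invert/swap flags
  writeBin(length(t$streamlines), con, size = 4L, endian = "little") # n_count
  writeBin(2L, con, size = 4L, endian = "little")               # version
  writeBin(TRK_HDR_SIZE, con, size = 4L, endian = "little")     # hdr_size
  for (s in t$streamlines) {
    vox <- affine_apply_points(affine_matrix(inv), s) + 0.5
    pts <- sweep(vox, 2L, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.vector(t(pts)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
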