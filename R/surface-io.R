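#' Cortical surface meshes
#'
#' Triangulated meshes with vertices in millimetres. FreeSurfer stores
#' surface coordinates in its "tkr" space, offset from scanner space by the
#' volume's RAS centre (cras); `space_tag` records which space the vertices
#' are currently in and [surface_to_world()] applies the shift.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param space_tag `"tkr"` or `"world"`.
#' @param cras_offset 3-vector added to tkr coordinates to reach world mm.
#' @return An `fsub_surface` list.
#' @export
surface_mesh <- function(vertices, faces, space_tag = c("world", "tkr"),
                         cras_offset = c(0, 0, 0)) {
  space_tag <- match.arg(space_tag)
  vertices <- as_points_matrix(vertices)
  if (any(!is.finite(vertices))) abort_validation("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) abort_validation("faces must be triangles (3 columns)")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      abort_validation("face indices must reference existing vertices")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    if (any(degen)) {
      abort_validation(sprintf("%d degenerate faces (repeated vertex indices)", sum(degen)))
    }
  }
  structure(list(vertices = vertices, faces = faces, space_tag = space_tag,
                 cras_offset = as.double(cras_offset)),
            class = "fsub_surface")
}

#' @export
print.fsub_surface <- function(x, ...) {
  cat(sprintf("<fsub_surface> %d vertices, %d faces, space=%s\n",
              nrow(x$vertices), nrow(x$faces), x$space_tag))
  invisible(x)
}

#' Shift a surface from tkr space into world mm
#'
#' Adds the cras offset once; world-space meshes pass through unchanged.
#'
#' @param mesh A [surface_mesh()].
#' @return The mesh with `space_tag = "world"`.
#' @export
surface_to_world <- function(mesh) {
  if (identical(mesh$space_tag, "world")) return(mesh)
  mesh$vertices <- sweep(mesh$vertices, 2L, mesh$cras_offset, "+")
  mesh$space_tag <- "world"
  mesh
}

FS_TRIANGLE_MAGIC <- 16777214L  # 0xFF FF FE

read_int3_be <- function(con) {
  b <- as.integer(readBin(con, "raw", n = 3L))
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_int3_be <- function(con, x) {
  writeBin(as.raw(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)), con)
}

#' Read a FreeSurfer binary triangle surface
#'
#' Big-endian payload behind a 3-byte magic. Vertices are returned tagged as
#' tkr space; the cras offset is taken from the embedded volume-geometry
#' footer when present, else set to zero with a warning (the mesh then
#' coincides with world space only if the source volume was centred).
#'
#' @param path Path to a surface file (e.g., `lh.white`).
#' @return A [surface_mesh()] with `space_tag = "tkr"`.
#' @export
read_fs_surface <- function(path) {
  stopifnot_file_exists(path, "surface file")
  con <- file(path, "rb")
  on.exit(close(con))
  if (read_int3_be(con) != FS_TRIANGLE_MAGIC) {
    abort_format(sprintf("not a FreeSurfer triangle surface (bad magic): %s", path))
  }
  # Creation comment: bytes up to a "\n\n" pair.
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) abort_corrupt("surface file ended inside its comment header")
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", size = 4L, endian = "big")
  nf <- readBin(con, "integer", size = 4L, endian = "big")
  if (is.na(nv) || is.na(nf) || nv < 0L || nf < 0L) {
    abort_corrupt("surface file declares negative or missing counts")
  }
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf) {
    abort_corrupt(sprintf("surface file truncated: expected %d vertices / %d faces", nv, nf))
  }
  cras <- c(0, 0, 0)
  tag <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
  if (length(tag) == 3L && identical(tag, c(2L, 0L, 20L))) {
    info <- read_fs_volume_geometry(con)
    if (!is.null(info$cras)) cras <- info$cras
  } else {
    fsub_warn("surface file has no volume-geometry footer; assuming cras = (0, 0, 0)")
  }
  surface_mesh(matrix(v, ncol = 3L, byrow = TRUE),
               matrix(f, ncol = 3L, byrow = TRUE) + 1L,
               space_tag = "tkr", cras_offset = cras)
}

read_fs_volume_geometry <- function(con) {
  out <- list()
  for (key in c("valid", "filename", "volume", "voxelsize",
                "xras", "yras", "zras", "cras")) {
    line <- read_raw_line(con)
    if (is.null(line)) break
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) break
    val <- trimws(kv[2])
    if (key %in% c("voxelsize", "xras", "yras", "zras", "cras")) {
      out[[key]] <- scan(text = val, what = double(), quiet = TRUE)
    } else {
      out[[key]] <- val
    }
  }
  out
}

read_raw_line <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10)) return(rawToChar(bytes))
    bytes <- c(bytes, b)
  }
}

#' Write a FreeSurfer binary triangle surface
#'
#' @param mesh A [surface_mesh()]; tkr-space coordinates are written as-is
#'   with the cras offset recorded in the volume-geometry footer.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3_be(con, FS_TRIANGLE_MAGIC)
  writeChar("created by fsubr\n\n", con, eos = NULL)
  writeBin(nrow(mesh$vertices), con, size = 4L, endian = "big")
  writeBin(nrow(mesh$faces), con, size = 4L, endian = "big")
  writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.vector(t(mesh$faces - 1L)), con, size = 4L, endian = "big")
  writeBin(c(2L, 0L, 20L), con, size = 4L, endian = "big")
  cras <- mesh$cras_offset
  num3 <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeChar(paste0(
    "valid = 1  # volume info valid\n",
    "filename = synthetic\n",
    "volume = 256 256 256\n",
    "voxelsize = 1 1 1\n",
    "xras   = 1 0 0\n",
    "yras   = 0 1 0\n",
    "zras   = 0 0 1\n",
    sprintf("cras   = %s\n", num3(cras))
  ), con, eos = NULL)
  invisible(path)
}
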