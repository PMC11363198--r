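#' Vertex labels (FreeSurfer .label)
#'
#' A vertex label names a set of mesh vertices, optionally with one scalar
#' per vertex (FreeSurfer's fifth column). Indices are 1-based inside the
#' package and converted to/from FreeSurfer's 0-based convention on I/O.
#'
#' @param vertex_indices Integer vector of unique 1-based vertex indices.
#' @param values Optional numeric vector, one value per listed vertex.
#' @param hemisphere `"lh"` or `"rh"`.
#' @param coords Optional n x 3 matrix of vertex coordinates (kept for
#'   round-tripping `.label` files; not used by the geometry code).
#' @return An `fsub_label` list.
#' @export
vertex_label <- function(vertex_indices, values = NULL, hemisphere = c("lh", "rh"),
                         coords = NULL) {
  hemisphere <- match.arg(hemisphere)
  vertex_indices <- as.integer(vertex_indices)
  if (anyDuplicated(vertex_indices)) {
    abort_validation("label vertex indices must be unique")
  }
  if (length(vertex_indices) && min(vertex_indices) < 1L) {
    abort_validation("label vertex indices must be positive (1-based)")
  }
  if (!is.null(values)) {
    values <- as.double(values)
    if (length(values) != length(vertex_indices)) {
      abort_validation("need one value per labelled vertex")
    }
  }
  if (!is.null(coords)) coords <- as_points_matrix(coords)
  structure(list(vertex_indices = vertex_indices, values = values,
                 hemisphere = hemisphere, coords = coords),
            class = "fsub_label")
}

#' @export
print.fsub_label <- function(x, ...) {
  cat(sprintf("<fsub_label> %d vertices (%s)\n", length(x$vertex_indices),
              x$hemisphere))
  invisible(x)
}

#' @export
length.fsub_label <- function(x) length(x$vertex_indices)

#' Read a FreeSurfer ASCII .label file
#'
#' Layout: one comment line, a count line, then rows of
#' `index x y z value` with 0-based vertex indices.
#'
#' @param path Path to the `.label` file.
#' @param hemisphere `"lh"` or `"rh"` (FreeSurfer labels do not record it;
#'   defaults to `"lh"`).
#' @return A [vertex_label()] with 1-based indices and retained values.
#' @export
read_label <- function(path, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot_file_exists(path, "label file")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) abort_format(sprintf("label file too short: %s", path))
  declared <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(declared)) abort_format(sprintf("unparseable label count line: %s", path))
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != declared) {
    abort_corrupt(sprintf("label declares %d vertices but has %d rows: %s",
                          declared, length(rows), path))
  }
  if (declared == 0L) {
    return(vertex_label(integer(0), hemisphere = hemisphere))
  }
  m <- matrix(scan(text = paste(rows, collapse = "\n"), what = double(),
                   quiet = TRUE), ncol = 5L, byrow = TRUE)
  vertex_label(as.integer(m[, 1]) + 1L, values = m[, 5],
               hemisphere = hemisphere, coords = m[, 2:4, drop = FALSE])
}

#' Write a FreeSurfer ASCII .label file
#'
#' @param label A [vertex_label()].
#' @param path Output path.
#' @param mesh Optional [surface_mesh()] supplying vertex coordinates when
#'   the label carries none (zeros are written otherwise).
#' @return The path, invisibly.
#' @export
write_label <- function(label, path, mesh = NULL) {
  n <- length(label$vertex_indices)
  coords <- label$coords
  if (is.null(coords) && !is.null(mesh)) {
    coords <- mesh$vertices[label$vertex_indices, , drop = FALSE]
  }
  if (is.null(coords)) coords <- matrix(0, nrow = n, ncol = 3L)
  vals <- label$values
  if (is.null(vals)) vals <- rep(0, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#!ascii label, written by fsubr", as.character(n)), con)
  if (n > 0L) {
    writeLines(sprintf("%d  %.6f  %.6f  %.6f %.10f",
                       label$vertex_indices - 1L,
                       coords[, 1], coords[, 2], coords[, 3], vals), con)
  }
  invisible(path)
}

# Check a label against a mesh it claims to index.
validate_label_on_mesh <- function(label, mesh) {
  if (length(label$vertex_indices) &&
      max(label$vertex_indices) > nrow(mesh$vertices)) {
    abort_validation("label indexes vertices beyond the mesh")
  }
  invisible(label)
}
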