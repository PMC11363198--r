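#' Read an MRtrix TCK tractogram
#'
#' TCK stores world (scanner) millimetre coordinates natively, so no
#' conversion is applied. The text header must begin with the magic line
#' `mrtrix tracks`; binary data are float triplets with a NaN triplet
#' separating consecutive streamlines and an Inf triplet terminating the
#' stream. Only the `Float32LE` and `Float32BE` datatypes are accepted —
#' anything else is refused loudly rather than risk a silent misread.
#'
#' @param path Path to a `.tck` file.
#' @return A [tractogram()] in world RAS mm. When the header declares a
#'   `count`, it is checked against the number of streamlines parsed.
#' @export
read_tck <- function(path) {
  stopifnot_file_exists(path, "TCK file")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks")) {
    abort_format(sprintf("not a TCK file (missing 'mrtrix tracks' magic): %s", path))
  }
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) abort_corrupt("TCK header ended before END marker")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) hdr[[trimws(kv[1])]] <- trimws(kv[2])
  }
  datatype <- hdr[["datatype"]]
  if (is.null(datatype)) abort_format("TCK header declares no datatype")
  endian <- switch(datatype,
    Float32LE = "little",
    Float32BE = "big",
    abort_dialect(sprintf("unsupported TCK datatype '%s' (only Float32LE/Float32BE)", datatype)))
  if (is.null(hdr[["file"]])) abort_format("TCK header declares no file offset")
  offset <- as.integer(sub("^\\.\\s+", "", hdr[["file"]]))
  if (is.na(offset)) abort_format("unparseable TCK file offset")

  fsize <- file.size(path)
  seek(con, where = offset, origin = "start")
  n_floats <- (fsize - offset) %/% 4L
  raw_vals <- readBin(con, what = "numeric", n = n_floats, size = 4L, endian = endian)
  if (length(raw_vals) %% 3L != 0L) {
    abort_corrupt(sprintf("TCK data section truncated at byte %d: not a whole number of triplets",
                          offset + 4L * length(raw_vals)))
  }
  trip <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.nan(trip)) == 3L
  is_inf <- rowSums(is.infinite(trip)) == 3L
  term <- which(is_inf)
  if (length(term) == 0L) {
    abort_corrupt(sprintf("TCK data section truncated at byte %d: no Inf terminator",
                          fsize))
  }
  term <- term[1]
  if (any(!is.finite(trip[seq_len(term - 1L), ]) & !is.nan(trip[seq_len(term - 1L), ]))) {
    abort_corrupt("non-NaN non-finite coordinate before TCK terminator")
  }
  streamlines <- list()
  start <- 1L
  breaks <- c(which(is_nan[seq_len(term)]), term)
  for (b in breaks) {
    if (b > start) {
      streamlines[[length(streamlines) + 1L]] <- trip[start:(b - 1L), , drop = FALSE]
    }
    start <- b + 1L
  }
  if (!is.null(hdr[["count"]])) {
    declared <- as.integer(hdr[["count"]])
    if (!is.na(declared) && declared != length(streamlines)) {
      abort_corrupt(sprintf("TCK header declares count %d but %d streamlines parsed",
                            declared, length(streamlines)))
    }
  }
  out <- tractogram(streamlines)
  out$meta <- list(format = "tck", path = path,
                   declared_count = hdr[["count"]], datatype = datatype)
  out
}

#' Write an MRtrix TCK tractogram
#'
#' Writes `datatype: Float32LE` with a NaN triplet after every streamline and
#' a final Inf triplet, re-readable by [read_tck()] and by independent TCK
#' readers.
#'
#' @param t A [tractogram()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tck <- function(t, path) {
  if (!inherits(t, "fsub_tractogram")) abort_validation("write_tck needs a tractogram")
  n <- length(t$streamlines)
  header_for <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           sprintf("count: %d\n", n),
           "total_count: ", n, "\n",
           sprintf("file: . %d\n", offset),
           "END\n")
  }
  # The offset appears inside the header, so iterate until the header length
  # is consistent with the offset it declares.
  offset <- nchar(header_for(0), type = "bytes")
  repeat {
    new_offset <- nchar(header_for(offset), type = "bytes")
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_for(offset), con, eos = NULL)
  sep <- rep(NaN, 3)
  for (s in t$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4L, endian = "little")
    writeBin(sep, con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}
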