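#' @include geometry.R
NULL

## Keys written by writeTck itself; everything else in @header is carried
## through verbatim.
.TCK_RESERVED <- c("datatype", "count", "file")
.TCK_META_KEYS <- c("subject", "session", "connection", "hemisphere")

## Parse subject/session/connection/hemisphere from a
## `<subject>_<session>_<connection>_<hemi>.tck` filename; NULL if the name
## does not follow the convention.
.parseSidecarName <- function(path) {
  stem <- sub("\\.tck$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4L) return(NULL)
  sess <- suppressWarnings(as.integer(parts[2]))
  if (is.na(sess) || !(parts[3] %in% .CONNECTIONS) ||
      !(parts[4] %in% .HEMISPHERES))
    return(NULL)
  list(subject = parts[1], session = sess, connection = parts[3],
       hemisphere = parts[4])
}

#' Read an MRtrix TCK tractogram
#'
#' Reads a track file in the MRtrix TCK layout: an ASCII header opened by
#' the `mrtrix tracks` magic line and terminated by `END`, followed by
#' little-endian 32-bit float coordinate triplets, with streamlines
#' separated by a NaN triplet and the file terminated by an Inf triplet.
#' Coordinates are returned exactly as stored (no resampling or
#' reorientation). Subject/session/connection/hemisphere metadata are taken
#' from header keys of those names when present, else parsed from a
#' `<subject>_<session>_<connection>_<hemi>.tck` filename, else left unset.
#'
#' @param path path to a `.tck` file.
#' @return A [Tractogram-class].
#' @seealso [writeTck()]
#' @export
readTck <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  nl <- which(raw == as.raw(10L))
  if (!length(nl)) stop("malformed TCK header: no newline found")
  firstLine <- rawToChar(raw[seq_len(nl[1] - 1L)])
  if (firstLine != "mrtrix tracks")
    stop("malformed TCK header: first line is not 'mrtrix tracks' (got '",
         firstLine, "')")

  header <- character()
  offset <- NA_integer_
  lineStart <- nl[1] + 1L
  i <- 2L
  repeat {
    if (i > length(nl))
      stop("malformed TCK header: END keyword not found")
    line <- rawToChar(raw[seq.int(lineStart, nl[i] - 1L)])
    lineStart <- nl[i] + 1L
    i <- i + 1L
    if (line == "END") break
    m <- regmatches(line, regexec("^([^:]+): ?(.*)$", line))[[1]]
    if (length(m) != 3L)
      stop("malformed TCK header line: '", line, "'")
    key <- trimws(m[2]); val <- m[3]
    header[key] <- val
    if (key == "file") {
      fm <- regmatches(val, regexec("^\\. ([0-9]+)$", trimws(val)))[[1]]
      if (length(fm) != 2L)
        stop("malformed TCK header line: 'file: ", val,
             "' (only single-file '. <offset>' supported)")
      offset <- as.integer(fm[2])
    }
  }
  if (is.na(offset)) stop("malformed TCK header: missing 'file' key")
  dt <- if ("datatype" %in% names(header)) header[["datatype"]] else NULL
  if (is.null(dt) || !identical(trimws(dt), "Float32LE"))
    stop("malformed TCK header: datatype must be Float32LE")

  nFloats <- (length(raw) - offset) %/% 4L
  vals <- readBin(raw[seq.int(offset + 1L, offset + 4L * nFloats)],
                  "double", n = nFloats, size = 4L, endian = "little")
  if (length(vals) %% 3L != 0L)
    stop("truncated TCK binary section: incomplete coordinate triplet ",
         "(0 streamlines read)")
  trip <- matrix(vals, ncol = 3L, byrow = TRUE)

  streamlines <- list()
  cur <- 1L
  terminated <- FALSE
  for (r in seq_len(nrow(trip))) {
    if (any(is.infinite(trip[r, ]))) { terminated <- TRUE; break }
    if (anyNA(trip[r, ])) {
      if (r > cur)
        streamlines[[length(streamlines) + 1L]] <-
          trip[cur:(r - 1L), , drop = FALSE]
      cur <- r + 1L
    }
  }
  if (!terminated)
    stop("truncated TCK binary section: no Inf terminator (",
         length(streamlines), " streamline(s) read so far)")

  meta <- list(subject = NA_character_, session = NA_integer_,
               connection = NA_character_, hemisphere = NA_character_)
  side <- .parseSidecarName(path)
  if (!is.null(side)) meta[names(side)] <- side
  for (k in .TCK_META_KEYS)
    if (k %in% names(header)) meta[[k]] <- header[[k]]
  extra <- header[setdiff(names(header), .TCK_RESERVED)]

  tractogram(streamlines, subject = meta$subject,
             session = as.integer(meta$session),
             connection = meta$connection, hemisphere = meta$hemisphere,
             header = extra)
}

#' Write an MRtrix TCK tractogram
#'
#' Emits the MRtrix TCK layout (see [readTck()]). Coordinates are written
#' as little-endian 32-bit floats; `readTck(writeTck(t))` reproduces the
#' stored geometry bit-for-bit at that precision. Metadata fields that are
#' set are recorded as header keys, so the round trip preserves them.
#'
#' @param t a [Tractogram-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTck <- function(t, path) {
  stopifnot(is(t, "Tractogram"))
  validObject(t)

  lines <- c("mrtrix tracks", "datatype: Float32LE",
             sprintf("count: %d", length(t@streamlines)))
  meta <- c(subject = t@subject, session = as.character(t@session),
            connection = t@connection, hemisphere = t@hemisphere)
  for (k in names(meta))
    if (!is.na(meta[[k]])) lines <- c(lines, sprintf("%s: %s", k, meta[[k]]))
  extra <- t@header[setdiff(names(t@header), c(.TCK_RESERVED, .TCK_META_KEYS))]
  for (k in names(extra)) lines <- c(lines, sprintf("%s: %s", k, extra[[k]]))

  ## the 'file' line records the byte offset of the binary section, which
  ## depends on the header length including that very line; iterate to a
  ## fixed point (converges in <= 2 steps since only digit count changes)
  offset <- 0L
  repeat {
    hdr <- paste0(paste(c(lines, sprintf("file: . %d", offset), "END"),
                        collapse = "\n"), "\n")
    newOffset <- nchar(hdr, type = "bytes")
    if (newOffset == offset) break
    offset <- newOffset
  }

  payload <- unlist(lapply(t@streamlines, function(p)
    c(t(p), NaN, NaN, NaN)), use.names = FALSE)
  payload <- c(payload, Inf, Inf, Inf)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(payload, con, size = 4L, endian = "little")
  invisible(path)
}
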