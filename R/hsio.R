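# ENVI-header + BSQ on-disk format.  BSQ alone is headerless, so the de
# facto ASCII key = value sidecar (<path>.hdr) carries shape, container
# type, interleave and the wavelength grid.  12-bit samples travel in
# 16-bit containers.

.enviTypes <- c("1" = 1L, "12" = 2L, "2" = 2L)  # data type -> bytes/sample

parseEnviHeader <- function(hdrPath) {
  if (!file.exists(hdrPath))
    stop("header file not found: ", hdrPath)
  lines <- readLines(hdrPath, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*ENVI\\s*$", lines[1L]))
    stop("malformed header: missing ENVI magic line in ", hdrPath)
  txt <- paste(lines[-1L], collapse = "\n")
  kv <- list()
  # split on newlines but re-join lines inside { }
  open <- FALSE; cur <- ""
  outlines <- character()
  for (ln in strsplit(txt, "\n", fixed = TRUE)[[1L]]) {
    cur <- if (open) paste(cur, ln) else ln
    nopen <- lengths(regmatches(cur, gregexpr("\\{", cur)))
    nclose <- lengths(regmatches(cur, gregexpr("\\}", cur)))
    open <- nopen > nclose
    if (!open && nzchar(trimws(cur))) { outlines <- c(outlines, cur); cur <- "" }
  }
  for (ln in outlines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- tolower(trimws(substr(ln, 1L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    kv[[key]] <- val
  }
  kv
}

.hdrNum <- function(kv, key) {
  if (is.null(kv[[key]])) stop("malformed header: missing field '", key, "'")
  v <- suppressWarnings(as.numeric(kv[[key]]))
  if (is.na(v)) stop("malformed header: non-numeric field '", key, "'")
  v
}

.hdrList <- function(kv, key) {
  v <- kv[[key]]
  if (is.null(v)) return(NULL)
  v <- gsub("[{}]", "", v)
  as.numeric(strsplit(v, ",")[[1L]])
}

#' Read a BSQ hyperspectral cube with its ENVI header
#'
#' Reads a band-sequential binary cube described by an ENVI-style ASCII
#' header.  The header must declare \code{bands}, \code{lines} (rows),
#' \code{samples} (cols), \code{data type}, \code{interleave = bsq} and
#' \code{bit depth}, plus either an explicit \code{wavelength = \{...\}}
#' list or a \code{wavelength start}/\code{wavelength end} pair that is
#' linearly spaced inclusive of both endpoints.
#'
#' @param path path to the binary BSQ file; the header is looked up at
#'   \code{header}, defaulting to \code{<path>.hdr}.
#' @param header path to the ENVI header.
#' @return a [HyperCube] whose band order matches file order.
#' @export
readBSQ <- function(path, header = paste0(path, ".hdr")) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  kv <- parseEnviHeader(header)
  interleave <- tolower(kv[["interleave"]] %||% "")
  if (interleave != "bsq")
    stop("format error in field 'interleave': expected 'bsq', got '",
         interleave, "'")
  bands <- as.integer(.hdrNum(kv, "bands"))
  rows <- as.integer(.hdrNum(kv, "lines"))
  cols <- as.integer(.hdrNum(kv, "samples"))
  dtype <- as.character(as.integer(.hdrNum(kv, "data type")))
  if (!dtype %in% names(.enviTypes))
    stop("format error in field 'data type': unsupported type ", dtype)
  bytes <- .enviTypes[[dtype]]
  bitDepth <- as.integer(.hdrNum(kv, "bit depth"))
  byteOrder <- if (is.null(kv[["byte order"]])) 0L else
    as.integer(.hdrNum(kv, "byte order"))
  endian <- if (byteOrder == 0L) "little" else "big"
  n <- as.numeric(bands) * rows * cols
  fsize <- file.info(path)$size
  if (fsize != n * bytes)
    stop(sprintf(
      "format error: file length %d does not match declared shape %dx%dx%d (%d bytes/sample)",
      fsize, bands, rows, cols, bytes))
  wl <- .hdrList(kv, "wavelength")
  if (is.null(wl)) {
    if (is.null(kv[["wavelength start"]]) || is.null(kv[["wavelength end"]]))
      stop("format error in field 'wavelength': neither a wavelength list ",
           "nor a start/end range is declared")
    wl <- seq(.hdrNum(kv, "wavelength start"), .hdrNum(kv, "wavelength end"),
              length.out = bands)
  }
  if (length(wl) != bands)
    stop("format error in field 'wavelength': ", length(wl),
         " values for ", bands, " bands")
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "integer", n = n, size = bytes,
                 signed = (bytes > 2L), endian = endian)
  if (bytes == 2L && any(raw < 0))  # uint16 read as signed on some paths
    raw[raw < 0] <- raw[raw < 0] + 65536L
  # file order: band-major, each band row-major (line by line)
  arr <- aperm(array(as.numeric(raw), dim = c(cols, rows, bands)),
               c(3L, 2L, 1L))
  HyperCube(arr, wl, bitDepth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a HyperCube as BSQ with an ENVI header
#'
#' Stored samples must be integers within the cube's bit-depth range;
#' bit depths up to 8 use 1-byte containers, up to 16 use unsigned 16-bit.
#' The result round-trips bit-exactly through [readBSQ()].
#'
#' @param cube a valid [HyperCube].
#' @param path output path for the binary; the header is written to
#'   \code{<path>.hdr}.
#' @return \code{path}, invisibly.
#' @export
writeBSQ <- function(cube, path) {
  validObject(cube)
  if (cube@bitDepth > 16L)
    stop("bit depths above 16 are not supported on disk")
  vals <- cube@data
  if (max(abs(vals - round(vals))) > 1e-9)
    stop("stored samples must be integer-valued for on-disk BSQ")
  bytes <- if (cube@bitDepth <= 8L) 1L else 2L
  dtype <- if (bytes == 1L) 1L else 12L
  d <- dim(vals)
  hdr <- c(
    "ENVI",
    "description = { hsvreg hyperspectral cube }",
    sprintf("samples = %d", d[3L]),
    sprintf("lines = %d", d[2L]),
    sprintf("bands = %d", d[1L]),
    sprintf("data type = %d", dtype),
    "interleave = bsq",
    "byte order = 0",
    sprintf("bit depth = %d", cube@bitDepth),
    "wavelength units = nm",
    sprintf("wavelength = { %s }",
            paste(format(cube@wavelengths, trim = TRUE), collapse = ", ")))
  con <- file(path, "wb")
  ok <- FALSE
  on.exit(close(con))
  flat <- as.integer(round(aperm(vals, c(3L, 2L, 1L))))
  if (bytes == 2L) flat[flat > 32767L] <- flat[flat > 32767L] - 65536L
  writeBin(flat, con, size = bytes, endian = "little")
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Export a MaskStack as a multi-page TIFF
#'
#' One 8-bit page per band, foreground rendered white.
#'
#' @param stack a [MaskStack].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
exportMasks <- function(stack, path) {
  pages <- lapply(seq_len(nBands(stack)),
                  function(b) 1 * getBand(stack, b))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
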