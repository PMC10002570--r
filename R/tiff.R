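# Minimal baseline TIFF 6.0 codec: little-endian, uncompressed, single
# sample per pixel, one strip per page. Supports exactly the two pixel types
# the pipeline emits: 16-bit unsigned photon counts and 32-bit IEEE float
# parametric maps. No R TIFF package is available in the target environment,
# so the subset is implemented here and cross-checked against an external
# reader in the test suite.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

tiff_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == TIFF_TYPE_SHORT) {
    v <- as.integer(value)
    writeBin(c(ifelse(v > 32767L, v - 65536L, v), 0L), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a multi-page TIFF
#'
#' Baseline TIFF 6.0, little-endian, uncompressed, one strip per page.
#'
#' @param path Output file path.
#' @param arr Numeric array `rows x cols x pages` (a matrix is treated as one
#'   page).
#' @param type `"uint16"` (integer counts in `[0, 65535]`) or `"float32"`
#'   (IEEE single precision; `NA` is stored as NaN).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, arr, type = c("uint16", "float32")) {
  type <- match.arg(type)
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  h <- dim(arr)[1]; w <- dim(arr)[2]; npages <- dim(arr)[3]
  bps <- if (type == "uint16") 16L else 32L
  fmt <- if (type == "uint16") 1L else 3L
  if (type == "uint16") {
    rng <- range(arr, na.rm = TRUE)
    if (anyNA(arr) || rng[1] < 0 || rng[2] > 65535)
      stop("uint16 TIFF requires finite values in [0, 65535]")
  }
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  data_bytes <- h * w * (bps %/% 8L)
  page_bytes <- ifd_bytes + data_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")  # first IFD right after header
  for (p in seq_len(npages)) {
    ifd_off <- 8L + (p - 1L) * page_bytes
    data_off <- ifd_off + ifd_bytes
    next_off <- if (p < npages) ifd_off + page_bytes else 0L
    writeBin(n_entries, con, size = 2, endian = "little")
    tiff_entry(con, 256L, TIFF_TYPE_LONG, 1L, w)            # ImageWidth
    tiff_entry(con, 257L, TIFF_TYPE_LONG, 1L, h)            # ImageLength
    tiff_entry(con, 258L, TIFF_TYPE_SHORT, 1L, bps)         # BitsPerSample
    tiff_entry(con, 259L, TIFF_TYPE_SHORT, 1L, 1L)          # Compression
    tiff_entry(con, 262L, TIFF_TYPE_SHORT, 1L, 1L)          # Photometric
    tiff_entry(con, 273L, TIFF_TYPE_LONG, 1L, data_off)     # StripOffsets
    tiff_entry(con, 277L, TIFF_TYPE_SHORT, 1L, 1L)          # SamplesPerPixel
    tiff_entry(con, 278L, TIFF_TYPE_LONG, 1L, h)            # RowsPerStrip
    tiff_entry(con, 279L, TIFF_TYPE_LONG, 1L, data_bytes)   # StripByteCounts
    tiff_entry(con, 339L, TIFF_TYPE_SHORT, 1L, fmt)         # SampleFormat
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
    pix <- as.vector(t(arr[, , p]))                         # row-major
    if (type == "uint16") {
      v <- as.integer(round(pix))
      writeBin(ifelse(v > 32767L, v - 65536L, v), con, size = 2,
               endian = "little")
    } else {
      writeBin(as.numeric(pix), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

read_uint <- function(con, size) {
  if (size == 2)
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  else {
    v <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (v < 0) stop("TIFF offsets beyond 2 GiB are not supported")
    v
  }
}

#' Read a multi-page TIFF written by [write_tiff()]
#'
#' Understands the baseline uncompressed little-endian subset this package
#' writes (and equivalent files from other writers: multi-strip pages are
#' supported, compression and tiling are not).
#'
#' @param path TIFF file path.
#' @return Numeric (float32) or integer (uint16) array `rows x cols x pages`
#'   with attribute `sample_type`.
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 2) != "II")
    stop("only little-endian ('II') TIFF is supported")
  if (readBin(con, "integer", 1, size = 2, endian = "little") != 42L)
    stop("not a classic TIFF file")
  ifd_off <- read_uint(con, 4)
  pages <- list()
  stype <- NULL
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n <- read_uint(con, 2)
    tags <- list()
    for (i in seq_len(n)) {
      tag <- read_uint(con, 2)
      type <- read_uint(con, 2)
      count <- read_uint(con, 4)
      raw4 <- readBin(con, "raw", 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        raw = raw4)
    }
    next_off <- read_uint(con, 4)
    val <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) {
        if (!is.null(default)) return(default)
        stop("required TIFF tag ", tag, " missing")
      }
      sz <- if (e$type == TIFF_TYPE_SHORT) 2L else 4L
      nbytes <- sz * e$count
      if (nbytes <= 4L) {
        rcon <- rawConnection(e$raw)
        out <- readBin(rcon, "integer", e$count, size = sz,
                       signed = sz == 4L, endian = "little")
        close(rcon)
        out
      } else {
        rcon <- rawConnection(e$raw)
        off <- readBin(rcon, "integer", 1, size = 4, endian = "little")
        close(rcon)
        seek(con, off)
        readBin(con, "integer", e$count, size = sz,
                signed = sz == 4L, endian = "little")
      }
    }
    w <- val(256); h <- val(257); bps <- val(258)
    if (val(259, 1L) != 1L) stop("compressed TIFF is not supported")
    if (val(277, 1L) != 1L) stop("multi-sample TIFF is not supported")
    fmt <- val(339, 1L)
    offs <- val(273); bytecounts <- val(279)
    this_type <- if (bps == 16L && fmt == 1L) "uint16"
      else if (bps == 32L && fmt == 3L) "float32"
      else stop("unsupported pixel type: ", bps, "-bit, sample format ", fmt)
    if (is.null(stype)) stype <- this_type
    else if (stype != this_type) stop("mixed pixel types across pages")
    pix <- if (this_type == "uint16") integer(0) else numeric(0)
    for (k in seq_along(offs)) {
      seek(con, offs[k])
      nvals <- bytecounts[k] / (bps / 8L)
      pix <- c(pix, if (this_type == "uint16")
        readBin(con, "integer", nvals, size = 2, signed = FALSE,
                endian = "little")
        else readBin(con, "numeric", nvals, size = 4, endian = "little"))
    }
    if (length(pix) != w * h) stop("strip byte counts inconsistent with size")
    pages[[length(pages) + 1L]] <- t(matrix(pix, nrow = w))  # from row-major
    ifd_off <- next_off
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(if (stype == "uint16") 0L else 0, c(h, w, length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]]
  attr(arr, "sample_type") <- stype
  arr
}
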