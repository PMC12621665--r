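# Minimal baseline TIFF I/O for single-channel micrographs: little-endian,
# uncompressed, one sample per pixel, 8/16-bit unsigned integer or 32-bit
# float, arbitrary strip layout. Deliberately rejects anything fancier
# (compression, tiles, palettes, multi-page) with a clear error.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Read a single-channel uncompressed TIFF image
#'
#' Supports baseline little-endian TIFF with one sample per pixel and
#' uint8/uint16/float32 storage. Multi-page or compressed files are rejected.
#'
#' @param path path to the TIFF file.
#' @return numeric H x W matrix (row = y).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop_format("TIFF file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 8) stop_format("not a valid TIFF file (truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic[1:2], as.raw(c(0x49, 0x49)))) {
    stop_format("only little-endian ('II') TIFF is supported: ", path)
  }
  if (readBin(magic[3:4], "integer", size = 2L, endian = "little") != 42L) {
    stop_format("not a valid TIFF file (bad magic): ", path)
  }
  ifd_off <- readBin(con, "integer", size = 4L, endian = "little")
  if (ifd_off <= 0 || ifd_off >= sz) stop_format("corrupt TIFF IFD offset: ", path)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", size = 2L, endian = "little")
  if (n_entries <= 0) stop_format("empty TIFF IFD: ", path)
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", size = 2L, endian = "little")
    typ <- readBin(con, "integer", size = 2L, endian = "little")
    cnt <- readBin(con, "integer", size = 4L, endian = "little")
    val_raw <- readBin(con, "raw", n = 4L)
    entries[[i]] <- list(tag = tag, typ = typ, cnt = cnt, raw = val_raw)
  }
  next_ifd <- readBin(con, "integer", size = 4L, endian = "little")
  if (!is.na(next_ifd) && length(next_ifd) && next_ifd != 0L) {
    stop_format("multi-page TIFF is unsupported: ", path)
  }
  type_bytes <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  read_values <- function(e) {
    tb <- if (e$typ <= 5L) type_bytes[e$typ] else 4L
    total <- tb * e$cnt
    get_vals <- function(r) {
      if (e$typ == 3L) readBin(r, "integer", n = e$cnt, size = 2L,
                               signed = FALSE, endian = "little")
      else readBin(r, "integer", n = e$cnt, size = 4L, endian = "little")
    }
    if (total <= 4L) get_vals(e$raw)
    else {
      off <- readBin(e$raw, "integer", size = 4L, endian = "little")
      seek(con, off)
      get_vals(readBin(con, "raw", n = total))
    }
  }
  tagval <- function(name, default = NULL) {
    hit <- Filter(function(e) e$tag == TIFF_TAGS[[name]], entries)
    if (!length(hit)) return(default)
    read_values(hit[[1]])
  }
  W <- tagval("width"); H <- tagval("height")
  if (is.null(W) || is.null(H)) stop_format("TIFF missing dimensions: ", path)
  if ((tagval("compression", 1L))[1] != 1L) {
    stop_format("compressed TIFF is unsupported: ", path)
  }
  if ((tagval("spp", 1L))[1] != 1L) {
    stop_format("multi-channel TIFF is unsupported: ", path)
  }
  bits <- (tagval("bits", 1L))[1]
  fmt <- (tagval("sample_format", 1L))[1]
  offs <- tagval("strip_offsets")
  lens <- tagval("strip_bytes")
  if (is.null(offs)) stop_format("TIFF missing strip offsets: ", path)
  if (is.null(lens)) lens <- rep(W * H * bits / 8 / length(offs), length(offs))
  raw_data <- raw(0)
  for (i in seq_along(offs)) {
    seek(con, offs[i])
    raw_data <- c(raw_data, readBin(con, "raw", n = lens[i]))
  }
  n <- W * H
  vals <- if (fmt == 3L && bits == 32L) {
    readBin(raw_data, "double", n = n, size = 4L, endian = "little")
  } else if (fmt %in% c(1L, 4L) && bits == 16L) {
    readBin(raw_data, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  } else if (fmt %in% c(1L, 4L) && bits == 8L) {
    as.integer(readBin(raw_data, "raw", n = n))
  } else {
    stop_format("unsupported TIFF sample layout (bits = ", bits,
                ", format = ", fmt, "): ", path)
  }
  if (length(vals) < n) stop_format("truncated TIFF strip data: ", path)
  # TIFF rows are stored top-to-bottom, x fastest
  matrix(as.numeric(vals), nrow = H, ncol = W, byrow = TRUE)
}

#' Write a single-channel float32 TIFF image
#'
#' Emits baseline little-endian uncompressed TIFF with 32-bit IEEE float
#' samples in a single strip.
#'
#' @param pixels numeric H x W matrix (row = y).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pixels, path) {
  assert_that(is.matrix(pixels) && all(is.finite(pixels)),
              "pixels must be a finite numeric matrix")
  H <- nrow(pixels); W <- ncol(pixels)
  data_bytes <- W * H * 4L
  n_entries <- 10L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_off, con, size = 4L, endian = "little")
  writeBin(n_entries, con, size = 2L, endian = "little")
  entry <- function(tag, typ, cnt, val) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(typ), con, size = 2L, endian = "little")
    writeBin(as.integer(cnt), con, size = 4L, endian = "little")
    if (typ == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(val), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(val), con, size = 4L, endian = "little")
    }
  }
  entry(256L, 4L, 1L, W)             # ImageWidth
  entry(257L, 4L, 1L, H)             # ImageLength
  entry(258L, 3L, 1L, 32L)           # BitsPerSample
  entry(259L, 3L, 1L, 1L)            # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)      # StripOffsets
  entry(277L, 3L, 1L, 1L)            # SamplesPerPixel
  entry(278L, 4L, 1L, H)             # RowsPerStrip
  entry(279L, 4L, 1L, data_bytes)    # StripByteCounts
  entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
  writeBin(0L, con, size = 4L, endian = "little")  # next IFD
  writeBin(as.numeric(t(pixels)), con, size = 4L, endian = "little")
  invisible(path)
}
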