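# Minimal MRC2014 I/O. Only what micrograph screening needs: 2-D real images,
# little-endian, modes 0 (int8), 1 (int16), 2 (float32); writer emits mode 2.
# Data layout follows the standard: column (x) fastest, mapc/mapr/maps = 1/2/3.
# In-memory convention throughout the package: pixels is an H x W matrix with
# row = y, so pixels[i, j] is the intensity at (x = j-1, y = i-1), 0-based.

MRC_HEADER_BYTES <- 1024L

#' Read a 2-D MRC2014 image
#'
#' @param path path to an MRC file (modes 0, 1 or 2; single section).
#' @return numeric H x W matrix of intensities (row = y).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop_format("MRC file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < MRC_HEADER_BYTES) {
    stop_format("not a valid MRC file (truncated header): ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head_i <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- head_i[1]; ny <- head_i[2]; nz <- head_i[3]; mode <- head_i[4]
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e6 || ny > 1e6) {
    stop_format("not a valid MRC file (bad dimensions): ", path)
  }
  if (nz != 1L) {
    stop_format("multi-frame MRC stacks are unsupported (nz = ", nz, "): ", path)
  }
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  n <- as.numeric(nx) * ny
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  if (is.na(bytes_per)) stop_format("unsupported MRC mode ", mode, ": ", path)
  need <- MRC_HEADER_BYTES + nsymbt + n * bytes_per
  if (sz < need) stop_format("truncated MRC data block: ", path)
  seek(con, MRC_HEADER_BYTES + nsymbt)
  vals <- switch(as.character(mode),
    `0` = readBin(con, "integer", n = n, size = 1L, signed = TRUE),
    `1` = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, "double", n = n, size = 4L, endian = "little"))
  if (any(!is.finite(vals))) stop_format("non-finite pixel values in ", path)
  # file stores x fastest: matrix(nrow = nx) has [x, y]; transpose to H x W
  t(matrix(as.numeric(vals), nrow = nx, ncol = ny))
}

#' Write a 2-D image as MRC2014 mode 2 (float32)
#'
#' @param pixels numeric H x W matrix (row = y).
#' @param path output path.
#' @param pixel_size optional pixel size in Angstrom per pixel, stored in the
#'   cell dimensions.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(pixels, path, pixel_size = 1) {
  assert_that(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  assert_that(all(is.finite(pixels)), "pixels must be finite")
  H <- nrow(pixels); W <- ncol(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(W, H, 1L, 2L))               # nx ny nz mode
  wi(c(0L, 0L, 0L))                 # nxstart nystart nzstart
  wi(c(W, H, 1L))                   # mx my mz
  wf(c(W * pixel_size, H * pixel_size, pixel_size))  # cella
  wf(c(90, 90, 90))                 # cellb
  wi(c(1L, 2L, 3L))                 # mapc mapr maps
  wf(c(min(pixels), max(pixels), mean(pixels)))      # dmin dmax dmean
  wi(0L)                            # ispg
  wi(0L)                            # nsymbt
  writeBin(raw(8L), con)            # extra (25-26)
  writeChar("MRCO", con, nchars = 4L, eos = NULL)    # exttyp
  wi(20140L)                        # nversion
  writeBin(raw(84L), con)           # remaining extra space
  wf(c(0, 0, 0))                    # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst little-endian
  wf(stats::sd(as.vector(pixels)))  # rms
  wi(0L)                            # nlabl
  writeBin(raw(800L), con)          # labels
  # data: x fastest -> write t(pixels) column-major
  writeBin(as.numeric(t(pixels)), con, size = 4L, endian = "little")
  invisible(path)
}
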