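# MRC2014 image I/O (mode 2, 32-bit float, little-endian).  The format is a
# 1024-byte header followed by raw pixel data, x fastest; pixel size is
# carried in the cell dimensions (cella / mx).

#' Write a micrograph to an MRC2014 file
#'
#' Mode 2 (32-bit IEEE float), little-endian, single section; the pixel size
#' is stored in the unit-cell field so that write -> read round-trips both
#' the pixels (bit-exact at float precision) and the calibration.
#'
#' @param m A [micrograph()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  nx <- nrow(m$pixels); ny <- ncol(m$pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  px <- as.numeric(m$pixels)
  wi(c(nx, ny, 1L))           # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(c(nx, ny, 1L))           # mx my mz
  wf(c(nx * m$pixel_size, ny * m$pixel_size, m$pixel_size))  # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(px), max(px), mean(px)))  # dmin dmax dmean
  wi(0L)                      # ispg
  wi(0L)                      # nsymbt
  writeBin(raw(100), con)     # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(px))           # rms
  wi(1L)                      # nlabl
  lab <- sprintf("%-80s", "peptoidsheet synthetic micrograph")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeBin(raw(80 * 9), con)
  writeBin(px, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file into a micrograph
#'
#' Supports mode 2 (float32) natively; mode 1 (int16) and mode 0 (int8) are
#' converted to float with a warning.  Other modes raise an error naming the
#' mode.  Multi-section files yield the first section.
#'
#' @param path MRC file path.
#' @return A [micrograph()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  ri(3)          # nxstart..
  mxyz <- ri(3)  # mx my mz
  cella <- rf(3)
  pixel_size <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  seek(con, 92)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- dims[1] * dims[2]
  px <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "1" = {
      warning("MRC mode 1 (int16) converted to float")
      as.numeric(readBin(con, "integer", n, size = 2, endian = "little"))
    },
    "0" = {
      warning("MRC mode 0 (int8) converted to float")
      as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE))
    },
    stop("unsupported MRC mode ", mode,
         ": only modes 0, 1 and 2 are readable"))
  micrograph(matrix(px, dims[1], dims[2]), pixel_size)
}
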