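# Minimal MRC (mode 2, 32-bit float) reader/writer for density grids and
# projection images. Little-endian, 1024-byte header, no extended header.

#' Write a density grid or projection image to an MRC file
#'
#' @param x a [DensityGrid-class] or [ProjectionImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(x, path) {
  if (is(x, "DensityGrid")) {
    data <- x@voxels; cellStep <- x@voxelSize; origin <- x@origin
    dims <- dim(data)
  } else if (is(x, "ProjectionImage")) {
    data <- x@pixels; cellStep <- x@pixelSize; origin <- c(0, 0, 0)
    dims <- c(dim(data), 1L)
  } else stop("x must be a DensityGrid or ProjectionImage")
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(v) writeBin(as.integer(v), con, size = 4,
                               endian = "little")
  wFlt <- function(v) writeBin(as.numeric(v), con, size = 4,
                               endian = "little")
  wInt(dims)                 # nx ny nz
  wInt(2L)                   # mode 2 = float32
  wInt(c(0L, 0L, 0L))        # nxstart nystart nzstart
  wInt(dims)                 # mx my mz
  wFlt(dims * cellStep)      # cella
  wFlt(c(90, 90, 90))        # cellb
  wInt(c(1L, 2L, 3L))        # mapc mapr maps
  wFlt(c(min(data), max(data), mean(data)))
  wInt(0L)                   # ispg
  wInt(0L)                   # nsymbt
  writeBin(raw(100), con)    # extra
  wFlt(origin)               # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machst (little-endian)
  wFlt(stats::sd(data))
  wInt(0L)                   # nlabl
  writeBin(raw(800), con)    # labels
  wFlt(as.numeric(data))
  invisible(path)
}

#' Read an MRC file
#'
#' Supports mode 2 (float32) maps as written by [writeMRC()] and common EM
#' software. A file with nz = 1 is returned as a projection image.
#'
#' @param path MRC file path.
#' @return A [DensityGrid-class] (nz > 1) or [ProjectionImage-class]
#'   (nz = 1).
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(k) readBin(con, "integer", n = k, size = 4,
                              endian = "little")
  rFlt <- function(k) readBin(con, "numeric", n = k, size = 4,
                              endian = "little")
  dims <- rInt(3)
  mode <- rInt(1)
  if (mode != 2) stop("only MRC mode 2 (float32) is supported, got ", mode)
  rInt(3)            # nxstart..
  mx <- rInt(3)
  cella <- rFlt(3)
  rFlt(3)            # cellb
  rInt(3)            # axis order
  rFlt(3)            # dmin dmax dmean
  rInt(2)            # ispg nsymbt
  readBin(con, "raw", n = 100)
  origin <- rFlt(3)
  readBin(con, "raw", n = 4 + 4)  # MAP + machst
  rFlt(1)            # rms
  rInt(1)            # nlabl
  readBin(con, "raw", n = 800)
  data <- rFlt(prod(dims))
  step <- cella[1] / max(mx[1], dims[1])
  if (dims[3] == 1L)
    projectionImage(matrix(data, dims[1], dims[2]), step)
  else
    densityGrid(array(data, dim = dims), step, origin)
}
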