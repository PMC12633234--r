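# MRC2014 reader/writer, mode 2 (32-bit float), little-endian.
# Axis convention: the fastest-varying file axis is x (columns), then y
# (rows), then z (sections); sections are image slices for stacks. Volumes
# are stored from the package's [x, y, z] grid directly; image stacks
# (indexed [y, x, image] in R) are transposed per image on write and
# restored on read.

#' Write a volume or image stack as MRC
#'
#' @param obj A [real_voxel_volume()], an [image_stack()], a
#'   [projection_image()], or a plain 2D/3D numeric array.
#' @param path Output file path.
#' @param voxel_size Voxel/pixel size in Angstrom; taken from `obj` when it
#'   carries one.
#' @param is_stack Treat a 3D array's third axis as images rather than
#'   z-sections (sets the MRC space-group word to 0). Inferred for
#'   `image_stack` input.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(obj, path, voxel_size = NULL, is_stack = FALSE) {
  if (inherits(obj, "real_voxel_volume")) {
    data <- obj$grid; voxel_size <- obj$voxel_size
  } else if (inherits(obj, "image_stack")) {
    data <- aperm(obj$pixels, c(2, 1, 3))  # -> [x, y, image]
    voxel_size <- obj$cfg$pixel_size; is_stack <- TRUE
  } else if (inherits(obj, "projection_image")) {
    data <- t(obj$pixels); voxel_size <- obj$pixel_size
  } else if (is.array(obj) || is.matrix(obj)) {
    data <- obj
    if (is_stack && length(dim(data)) == 3) data <- aperm(data, c(2, 1, 3))
  } else stopf("cannot write object of class %s as MRC", class(obj)[1])
  if (is.null(voxel_size)) stopf("voxel_size is required for bare arrays")
  d <- dim(data)
  if (length(d) == 2) d <- c(d, 1L)
  dim(data) <- d
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                     # nx, ny, nz
  wi(2)                     # mode 2: float32
  wi(c(0, 0, 0))            # nxstart
  wi(d)                     # mx, my, mz
  wf(d * voxel_size)        # cella
  wf(c(90, 90, 90))         # cellb
  wi(c(1, 2, 3))            # mapc, mapr, maps
  wf(c(min(data), max(data), mean(data)))
  wi(if (is_stack) 0 else 1)  # ispg
  wi(0)                     # nsymbt
  wi(rep(0, 25))            # extra
  wf(c(0, 0, 0))            # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp, LE
  wf(stats::sd(data))       # rms
  wi(1)                     # nlabl
  lab <- formatC("Written by cryosim", width = -80)
  writeChar(lab, con, 80, eos = NULL)
  writeBin(raw(720), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC volume or stack
#'
#' @param path MRC file path (mode 0/1/2 supported; data returned as
#'   double).
#' @return A list with `data` (3D array; volumes as `[x, y, z]`, stacks as
#'   `[y, x, image]`), `voxel_size` (Angstrom), and `is_stack`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                     # nxstart
  mx <- ri(3)
  cella <- rf(3)
  rf(3)                     # cellb
  mapcrs <- ri(3)
  rf(3)                     # dmin/dmax/dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  ri(25); rf(3)
  maptag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(maptag, "MAP ")) stopf("not an MRC2014 file: %s", path)
  readBin(con, "raw", 4)
  rf(1); ri(1)
  readBin(con, "raw", 800)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stopf("unsupported MRC mode %d", mode))
  if (length(data) != n) stopf("truncated MRC data in %s", path)
  dim(data) <- d
  voxel_size <- if (mx[1] > 0) cella[1] / mx[1] else 1
  is_stack <- ispg == 0 && d[3] > 1
  if (is_stack || d[3] == 1) data <- aperm(data, c(2, 1, 3))
  list(data = data, voxel_size = voxel_size, is_stack = is_stack)
}

#' Read an MRC volume as a real_voxel_volume
#' @param path MRC file path holding a cubic volume.
#' @return A [real_voxel_volume()].
#' @export
read_mrc_volume <- function(path) {
  m <- read_mrc(path)
  if (m$is_stack) stopf("%s is an image stack, not a volume", path)
  real_voxel_volume(m$data, m$voxel_size)
}
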