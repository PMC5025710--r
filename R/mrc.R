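# MRC2014 I/O (modes 0/1/2). The header is the fixed 1024-byte block; the
# only extended-header content honoured is its size (nsymbt), which is
# skipped on read. Voxel size is cell length / sampling.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC map or image
#'
#' Reads an MRC2014 file (modes 0, 1 or 2). A file with `nz == 1` is
#' returned as an [image2d()]; otherwise a cubic [voxel_grid()] is
#' returned. Non-cubic 3D volumes are symmetrically zero-padded to a cube
#' when `pad = TRUE` (default) or rejected otherwise.
#'
#' @param path file path.
#' @param pad pad non-cubic volumes to a cube instead of erroring.
#' @param tol relative tolerance on voxel anisotropy (default 1e-3); files
#'   with more anisotropic voxels are rejected.
#' @return a [voxel_grid()] or [image2d()].
#' @export
read_mrc <- function(path, pad = TRUE, tol = 1e-3) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_raw <- readBin(con, "raw", MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES) stop("malformed MRC header: file too short")
  rd_int <- function(off, n = 1, e = endian)
    readBin(hdr_raw[(off + 1):(off + 4 * n)], "integer", n, size = 4, endian = e)
  rd_flt <- function(off, n = 1, e = endian)
    readBin(hdr_raw[(off + 1):(off + 4 * n)], "double", n, size = 4, endian = e)
  nxyz <- rd_int(0, 3)
  if (any(nxyz <= 0) || any(nxyz > 1e5)) {
    # try big-endian
    nxyz_be <- rd_int(0, 3, "big")
    if (all(nxyz_be > 0) && all(nxyz_be <= 1e5)) {
      endian <- "big"
      nxyz <- nxyz_be
    } else stop("malformed MRC header: implausible dimensions")
  }
  mode <- rd_int(12)
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " (only 0/1/2)")
  mxyz <- rd_int(28, 3)
  cella <- rd_flt(40, 3)
  nsymbt <- rd_int(92)
  orig <- rd_flt(196, 3)
  if (any(mxyz <= 0)) mxyz <- nxyz
  vs <- cella / mxyz
  if (any(vs <= 0)) stop("malformed MRC header: non-positive cell")
  if (max(vs) - min(vs) > tol * mean(vs))
    stop(sprintf("anisotropic voxels (%.4g/%.4g/%.4g A); not supported",
                 vs[1], vs[2], vs[3]))
  voxel_size <- mean(vs)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE,
                             endian = endian)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "double", nvox, size = 4, endian = endian))
  if (length(data) < nvox) stop("malformed MRC file: truncated data block")
  if (nxyz[3] == 1L) {
    m <- matrix(data, nxyz[1], nxyz[2])
    if (nxyz[1] != nxyz[2])
      stop("2D MRC image is not square (", nxyz[1], "x", nxyz[2], ")")
    return(image2d(m, voxel_size))
  }
  arr <- array(data, dim = nxyz)
  if (nxyz[1] != nxyz[2] || nxyz[2] != nxyz[3]) {
    if (!pad)
      stop("non-cubic volume ", paste(nxyz, collapse = "x"),
           "; re-read with pad = TRUE to zero-pad")
    return(pad_to_cube(arr, voxel_size, orig))
  }
  voxel_grid(arr, voxel_size, orig)
}

#' Write an MRC map or image
#'
#' Writes a [voxel_grid()] or [image2d()] as MRC2014 mode 2 (float32).
#' Round-trips bit-exactly with [read_mrc()] for float32 data.
#'
#' @param x a [voxel_grid()] or [image2d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  if (is_voxel_grid(x)) {
    dims <- dim(x$data); vs <- x$voxel_size; data <- x$data
    orig <- x$origin
  } else if (is_image2d(x)) {
    dims <- c(dim(x$data), 1L); vs <- x$pixel_size; data <- x$data
    orig <- c(0, 0, 0)
  } else stop("`x` must be a voxel_grid or image2d")
  if (anyNA(data) || any(!is.finite(data))) stop("non-finite data")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(dims)                       # nx ny nz
  wi(2L)                         # mode 2 = float32
  wi(c(0L, 0L, 0L))              # nxstart
  wi(dims)                       # mx my mz
  wf(dims * vs)                  # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1L, 2L, 3L))              # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(0L)                         # ispg
  wi(0L)                         # nsymbt
  writeBin(raw(100L), con)       # extra (incl. exttyp/nversion left zero)
  wf(orig)                       # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(data)))
  wi(0L)                         # nlabl
  writeBin(raw(800L), con)       # labels
  wf(data)
  invisible(path)
}
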