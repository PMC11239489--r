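#' Read an MRC2014 volume
#'
#' Reads a mode-2 (32-bit float) MRC2014 map, canonicalizing the axis order so
#' that the returned grid is indexed `[x, y, z]` with x fastest, regardless of
#' the header's `MAPC/MAPR/MAPS` fields. The voxel size is taken from the
#' header as cell length divided by the number of grid samples and must be
#' isotropic within 0.1%.
#'
#' @param path path to an MRC file.
#' @param pad_to_cube if `TRUE`, a non-cubic or odd-edged map is padded to the
#'   smallest enclosing even cube with edge-value fill; otherwise such maps are
#'   rejected.
#' @return A [volume()].
#' @export
read_mrc <- function(path, pad_to_cube = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("malformed header: file shorter than the 1024-byte MRC header")
  int_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "integer", size = 4, endian = "little")
  dbl_at <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                   "numeric", size = 4, endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  if (mode != 2L) stop("unsupported MRC MODE ", mode, " (only mode 2, 32-bit float, is supported)")
  if (any(c(nx, ny, nz) <= 0L)) stop("malformed header: non-positive NX/NY/NZ")
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(dbl_at(11), dbl_at(12), dbl_at(13))
  mapc <- int_at(17); mapr <- int_at(18); maps <- int_at(19)
  nsymbt <- int_at(24)
  orig <- c(dbl_at(50), dbl_at(51), dbl_at(52))
  if (!all(sort(c(mapc, mapr, maps)) == 1:3))
    stop("malformed header: MAPC/MAPR/MAPS is not a permutation of 1,2,3")
  if (any(c(mx, my, mz) <= 0L)) stop("malformed header: non-positive MX/MY/MZ")
  vox <- cella / c(mx, my, mz)
  if (any(vox <= 0)) stop("malformed header: CELLA implies non-positive voxel size")
  if (max(vox) / min(vox) > 1.001)
    stop("anisotropic voxel size in CELLA is not supported: ",
         paste(signif(vox, 6), collapse = ", "))
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- as.double(nx) * ny * nz
  dat <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(dat) < nvox) stop("truncated file: expected ", nvox, " voxels, got ", length(dat))
  arr <- array(dat, c(nx, ny, nz))  # file axis order: MAPC fastest
  # file axes (fast, medium, slow) hold data axes (mapc, mapr, maps);
  # permute so output axis i is data axis i (x, y, z)
  perm <- match(1:3, c(mapc, mapr, maps))
  arr <- aperm(arr, perm)
  d <- dim(arr)
  if (d[1] != d[2] || d[2] != d[3] || d[1] %% 2L != 0L || d[1] < 16L) {
    if (!pad_to_cube)
      stop("NX/NY/NZ = ", paste(d, collapse = "x"),
           " is not an even cube of edge >= 16; pass pad_to_cube = TRUE to pad")
    arr <- pad_to_even_cube(arr)
  }
  volume(arr, mean(vox), orig)
}

#' Write an MRC2014 volume
#'
#' Writes mode-2 (32-bit float) MRC2014 with `MAPC/MAPR/MAPS = 1,2,3`, cell
#' dimensions `n * voxel_size`, and the volume origin in the MRC2014 origin
#' fields.
#'
#' @param vol a [volume()].
#' @param path destination path.
#' @export
write_mrc <- function(vol, path) {
  if (!is_volume(vol)) stop("vol must be a blush_volume")
  if (!all(is.finite(vol$grid))) stop("grid contains non-finite values; refusing to write")
  write_mrc_array(vol$grid, vol$voxel_size, vol$origin, path)
}

# Shared writer; also used for image stacks (nz = number of images).
write_mrc_array <- function(arr, voxel_size, origin, path, stack = FALSE) {
  if (!all(is.finite(arr))) stop("array contains non-finite values; refusing to write")
  d <- dim(arr)
  con <- tryCatch(file(path, "wb"), error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                        # NX NY NZ
  wi(2L)                       # MODE 2
  wi(c(0L, 0L, 0L))            # NXSTART..
  mxyz <- if (stack) c(d[1], d[2], 1L) else d
  wi(mxyz)                     # MX MY MZ
  wf(mxyz * voxel_size)        # CELLA
  wf(c(90, 90, 90))            # CELLB
  wi(1:3)                      # MAPC MAPR MAPS
  wf(c(min(arr), max(arr), mean(arr)))  # DMIN DMAX DMEAN
  wi(if (stack) 0L else 1L)    # ISPG (0 = image stack)
  wi(0L)                       # NSYMBT
  wi(rep(0L, 25))              # EXTRA (words 26-49, incl. EXTTYP/NVERSION left 0)
  wf(origin)                   # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.vector(arr)))  # RMS
  wi(0L)                       # NLABL
  writeBin(raw(800), con)      # labels
  wf(as.vector(arr))
  invisible(path)
}

#' Write / read a stack of 2D images as an MRC stack (.mrcs)
#'
#' @param images array `(nx, ny, n_images)`.
#' @param pixel_size pixel size in Angstrom.
#' @param path destination path.
#' @return `read_mrcs_stack` returns `list(images, pixel_size)`.
#' @export
write_mrcs_stack <- function(images, pixel_size, path) {
  if (length(dim(images)) != 3L) stop("images must be (nx, ny, n) array")
  write_mrc_array(images, pixel_size, c(0, 0, 0), path, stack = TRUE)
}

#' @rdname write_mrcs_stack
#' @export
read_mrcs_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 1024L)
  if (length(hdr) < 1024L) stop("malformed header")
  int_at <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "integer", size = 4, endian = "little")
  dbl_at <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "numeric", size = 4, endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  if (int_at(4) != 2L) stop("unsupported MRC MODE for stack")
  px <- dbl_at(11) / int_at(8)
  nvox <- as.double(nx) * ny * nz
  dat <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(dat) < nvox) stop("truncated file")
  list(images = array(dat, c(nx, ny, nz)), pixel_size = px)
}
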