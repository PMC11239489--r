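#' Construct a density volume
#'
#' A `blush_volume` is the package's universal container: a cubic 3D grid of
#' density values together with its isotropic voxel size in Angstrom and the
#' physical origin of the grid corner. Grids are indexed `[x, y, z]` with the
#' first index fastest in memory, matching the canonical MRC axis order.
#'
#' Grids are constrained to be cubic with an even edge of at least 16 voxels:
#' an even edge gives an unambiguous Nyquist shell at `n/2`, which the
#' Fourier-shell machinery relies on throughout.
#'
#' @param grid 3D numeric array of density values (arbitrary units).
#' @param voxel_size voxel edge length in Angstrom (> 0, isotropic).
#' @param origin physical offset of the grid corner, Angstrom (length 3).
#' @return An object of class `blush_volume` with fields `grid`, `voxel_size`,
#'   `origin`.
#' @export
volume <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  d <- dim(grid)
  if (d[1] != d[2] || d[2] != d[3])
    stop("grid must be cubic; got ", paste(d, collapse = "x"))
  if (d[1] < 16L || d[1] %% 2L != 0L)
    stop("grid edge must be even and >= 16; got ", d[1])
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  if (!all(is.finite(grid)))
    stop("grid contains non-finite values")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "blush_volume")
}

#' @export
print.blush_volume <- function(x, ...) {
  n <- dim(x$grid)[1]
  cat(sprintf("<blush_volume %d^3, %.4g A/voxel, extent %.4g A, range [%.3g, %.3g]>\n",
              n, x$voxel_size, n * x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "blush_volume")

# Accept a volume or bare 3D array; return the array.
vol_grid <- function(v) if (is_volume(v)) v$grid else v

vol_edge <- function(v) dim(vol_grid(v))[1]

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(vol_grid(a)), dim(vol_grid(b))))
    stop("volumes must have identical dimensions")
  if (is_volume(a) && is_volume(b) &&
      abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    stop("volumes must have identical voxel sizes")
  invisible(TRUE)
}

# Replace the grid, keeping metadata.
with_grid <- function(v, grid) {
  if (is_volume(v)) volume(grid, v$voxel_size, v$origin) else grid
}

#' Pad a (possibly non-cubic) array to an even cube
#'
#' Pads with the edge value of each face so that smooth solvent backgrounds
#' stay smooth. Used by [read_mrc()] behind an explicit flag; internal code
#' always assumes cubic, even grids.
#'
#' @param arr 3D array.
#' @return 3D array padded to the smallest enclosing even cube.
#' @keywords internal
pad_to_even_cube <- function(arr) {
  d <- dim(arr)
  n <- max(d)
  if (n %% 2L != 0L) n <- n + 1L
  n <- max(n, 16L)
  if (all(d == n)) return(arr)
  out <- array(0, c(n, n, n))
  lo <- floor((n - d) / 2) + 1L
  hi <- lo + d - 1L
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- arr
  # edge-value fill outward along each axis
  fill_axis <- function(a, axis, lo, hi) {
    n <- dim(a)[axis]
    idx <- function(i) switch(axis, a[i, , ], a[, i, ], a[, , i])
    set <- function(i, val) {
      if (axis == 1) a[i, , ] <<- val
      else if (axis == 2) a[, i, ] <<- val
      else a[, , i] <<- val
    }
    if (lo > 1) for (i in seq_len(lo - 1)) set(i, idx(lo))
    if (hi < n) for (i in (hi + 1):n) set(i, idx(hi))
    a
  }
  for (ax in 1:3) out <- fill_axis(out, ax, lo[ax], hi[ax])
  out
}
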