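#' Tile a volume into overlapping cubic patches
#'
#' Computes patch origins that cover the whole grid and per-patch blending
#' weights for seamless re-assembly. Weights are separable raised-cosine ramps
#' over the overlap region, renormalized per axis so that at every voxel the
#' contributing weights sum to one (a partition of unity). Patches at the
#' volume boundary keep full weight up to the boundary.
#'
#' @param vol a [volume()] or 3D array.
#' @param patch_edge patch edge in voxels (default 64).
#' @param overlap overlap between adjacent patches in voxels,
#'   `0 <= overlap < patch_edge`.
#' @return A `blush_patch_grid`: `n`, `patch_edge`, `origins` (k x 3 matrix of
#'   1-based corner indices) and `axis_weights` (per axis, a list of 1D weight
#'   vectors per origin).
#' @export
tile_volume <- function(vol, patch_edge = 64L, overlap = 0L) {
  n <- vol_edge(vol)
  patch_edge <- as.integer(patch_edge); overlap <- as.integer(overlap)
  if (patch_edge > n) stop("patch_edge exceeds volume edge")
  if (overlap < 0L || overlap >= patch_edge) stop("need 0 <= overlap < patch_edge")
  origins1 <- axis_origins(n, patch_edge, overlap)
  aw <- axis_blend_weights(n, patch_edge, overlap, origins1)
  og <- as.matrix(expand.grid(x = origins1, y = origins1, z = origins1))
  structure(list(n = n, patch_edge = patch_edge, overlap = overlap,
                 origins = og, origins1 = origins1, axis_weights = aw),
            class = "blush_patch_grid")
}

axis_origins <- function(n, e, v) {
  if (e == n) return(1L)
  stride <- e - v
  o <- seq(1L, n - e + 1L, by = stride)
  if (tail(o, 1) != n - e + 1L) o <- c(o, n - e + 1L)
  o
}

# Per-origin 1D weights (length e each), normalized so per-coordinate sums = 1.
axis_blend_weights <- function(n, e, v, origins) {
  m <- length(origins)
  raw <- vector("list", m)
  for (i in seq_len(m)) {
    w <- rep(1, e)
    if (v > 0) {
      t <- (seq_len(v) - 0.5) / v
      ramp <- 0.5 * (1 - cos(pi * t))
      if (origins[i] > 1L) w[seq_len(v)] <- ramp            # ramp up at leading edge
      if (origins[i] + e - 1L < n) w[e - v + seq_len(v)] <- rev(ramp)  # ramp down
    }
    raw[[i]] <- w
  }
  tot <- rep(0, n)
  for (i in seq_len(m)) {
    idx <- origins[i]:(origins[i] + e - 1L)
    tot[idx] <- tot[idx] + raw[[i]]
  }
  lapply(seq_len(m), function(i) {
    idx <- origins[i]:(origins[i] + e - 1L)
    raw[[i]] / tot[idx]
  })
}

# Full 3D blend weight array for patch j (product of axis weights).
patch_weight <- function(grid, j) {
  o <- grid$origins[j, ]
  ix <- match(o[1], grid$origins1); iy <- match(o[2], grid$origins1)
  iz <- match(o[3], grid$origins1)
  wx <- grid$axis_weights[[ix]]; wy <- grid$axis_weights[[iy]]
  wz <- grid$axis_weights[[iz]]
  outer(outer(wx, wy), wz)
}

#' Extract the patches of a tiling
#'
#' @param vol a [volume()] or 3D array.
#' @param grid a `blush_patch_grid` from [tile_volume()].
#' @return List of `patch_edge^3` arrays, one per row of `grid$origins`.
#' @export
extract_patches <- function(vol, grid) {
  g <- vol_grid(vol); e <- grid$patch_edge
  lapply(seq_len(nrow(grid$origins)), function(j) {
    o <- grid$origins[j, ]
    g[o[1]:(o[1] + e - 1L), o[2]:(o[2] + e - 1L), o[3]:(o[3] + e - 1L)]
  })
}

#' Stitch patches back into a volume
#'
#' Weighted sum of the patches using the tiling's partition-of-unity blend
#' weights; `stitch_patches(extract_patches(v, g), g)` reproduces `v` up to
#' floating-point roundoff.
#'
#' @param patches list of 3D arrays matching `grid`.
#' @param grid a `blush_patch_grid`.
#' @param template optional [volume()] supplying voxel size and origin for the
#'   result; if missing, a bare array is returned.
#' @export
stitch_patches <- function(patches, grid, template = NULL) {
  e <- grid$patch_edge
  if (length(patches) != nrow(grid$origins)) stop("patch list does not match grid")
  out <- array(0, rep(grid$n, 3))
  for (j in seq_along(patches)) {
    p <- patches[[j]]
    if (!identical(dim(p), rep(e, 3L)) && !identical(dim(p), as.integer(rep(e, 3))))
      stop("patch ", j, " has wrong shape")
    o <- grid$origins[j, ]
    idx <- lapply(o, function(oo) oo:(oo + e - 1L))
    out[idx[[1]], idx[[2]], idx[[3]]] <-
      out[idx[[1]], idx[[2]], idx[[3]]] + p * patch_weight(grid, j)
  }
  if (is.null(template)) out else with_grid(template, out)
}
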