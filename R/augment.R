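# Training-pair augmentation: each half-map pair yields input/target patches
#   y     = H_{C,A}[ x^(1-k) + e^(1-k) ]            (input, from the OTHER half)
#   ybar  = H_{Cbar,A}[ x^(k).M + h(x^(k)).(1-M) ]  (target, from half k)
# where H applies an anisotropic Gaussian filter, an affine transform, a crop
# to a cubic patch, and voxel-value standardization; h is a low-pass fill for
# disordered regions and M a smooth molecule mask. Input and target of one
# example share the same affine transform and crop, so the only differences
# the network can learn are the noise and the filter pair -- the noise2noise
# contract.

#' Half-map pair
#'
#' Two independently reconstructed volumes sharing signal but carrying
#' independent noise, plus an optional smooth molecule mask.
#'
#' @param x0,x1 [volume()]s of identical shape and voxel size.
#' @param mask optional [volume()] with values in `[0, 1]`.
#' @param id identifier string.
#' @export
halfmap_pair <- function(x0, x1, mask = NULL, id = "pair") {
  stopifnot_same_shape(x0, x1)
  if (!is.null(mask)) {
    stopifnot_same_shape(x0, mask)
    mg <- vol_grid(mask)
    if (min(mg) < -1e-9 || max(mg) > 1 + 1e-9) stop("mask values must lie in [0, 1]")
  }
  structure(list(x0 = x0, x1 = x1, mask = mask, id = id), class = "blush_halfmap_pair")
}

#' Rigid-body transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (within 1e-6).
#' @param translation length-3 shift in voxels.
#' @export
affine_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "blush_affine")
}

#' Uniform random rotation matrix
#'
#' Drawn uniformly over SO(3) via a normalized Gaussian quaternion.
#'
#' @param seed integer seed (`NULL` uses the current stream).
#' @export
random_rotation <- function(seed = NULL) {
  q <- with_seed(seed, rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# trilinear gather at real-valued coordinates (V x 3, 1-based); outside -> fill
trilinear_sample <- function(grid, coords, fill) {
  n <- dim(grid)
  i0 <- floor(coords)
  fr <- coords - i0
  inside <- coords[, 1] >= 1 & coords[, 1] <= n[1] &
            coords[, 2] >= 1 & coords[, 2] <= n[2] &
            coords[, 3] >= 1 & coords[, 3] <= n[3]
  i0c <- pmin(pmax(i0, 1), matrix(n - 1L, nrow(i0), 3, byrow = TRUE))
  frc <- pmin(pmax(coords - i0c, 0), 1)
  gx <- function(ix, iy, iz) grid[cbind(ix, iy, iz)]
  x0 <- i0c[, 1]; y0 <- i0c[, 2]; z0 <- i0c[, 3]
  fx <- frc[, 1]; fy <- frc[, 2]; fz <- frc[, 3]
  v <- gx(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
       gx(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
       gx(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
       gx(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
       gx(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
       gx(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
       gx(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
       gx(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  v[!inside] <- fill
  v
}

# source coordinates for output points p: q = R^T (p - c - t) + c
affine_source_coords <- function(p, A, n) {
  ctr <- (n + 1) / 2
  sweep(sweep(p, 2, ctr + A$translation) %*% A$rotation, 2, -ctr)
}

#' Standardize a patch to zero mean, unit standard deviation
#'
#' Uses the population standard deviation over the full patch. A patch with
#' (near-)zero variance cannot be standardized and is rejected with a
#' condition of class `blushr_zero_variance`.
#'
#' @param p numeric array.
#' @export
standardize_patch <- function(p) {
  m <- mean(p)
  s <- sqrt(mean((p - m)^2))
  if (!is.finite(s) || s < 1e-10)
    stop(structure(class = c("blushr_zero_variance", "error", "condition"),
                   list(message = "patch has (near-)zero variance; sample rejected",
                        call = sys.call(-1))))
  (p - m) / s
}

#' Apply the augmentation operator H
#'
#' In order: anisotropic Gaussian filter with covariance `C`; resampling under
#' the rigid transform `A` (trilinear interpolation, out-of-grid values filled
#' with the volume mean); crop to a `patch_edge`-cube at `crop_corner`; and
#' standardization to zero mean / unit standard deviation.
#'
#' @param v a [volume()].
#' @param C 3x3 Gaussian covariance (Angstrom^2); all-zero skips the filter.
#' @param A an [affine_transform()].
#' @param crop_corner 1-based corner index of the crop (length 3).
#' @param patch_edge crop edge in voxels (default 64).
#' @return `patch_edge`-cube array, standardized.
#' @export
apply_H <- function(v, C, A = affine_transform(), crop_corner = c(1, 1, 1),
                    patch_edge = 64L) {
  n <- vol_edge(v)
  e <- as.integer(patch_edge)
  crop_corner <- as.integer(crop_corner)
  if (any(crop_corner < 1L) || any(crop_corner + e - 1L > n))
    stop("crop out of bounds")
  vf <- if (all(C == 0)) v else anisotropic_gaussian_filter(v, C)
  g <- vol_grid(vf)
  idx <- lapply(crop_corner, function(o) o:(o + e - 1L))
  identity_A <- max(abs(A$rotation - diag(3))) < 1e-12 && all(A$translation == 0)
  if (identity_A) {
    p <- g[idx[[1]], idx[[2]], idx[[3]]]
  } else {
    pts <- as.matrix(expand.grid(x = idx[[1]], y = idx[[2]], z = idx[[3]]))
    q <- affine_source_coords(pts, A, n)
    p <- array(trilinear_sample(g, q, fill = mean(g)), rep(e, 3))
  }
  standardize_patch(p)
}

#' Augmentation policy
#'
#' Ranges for the random augmentation draws. Resolution cutoffs are in
#' Angstrom; the input-side cutoff is constrained to be no higher-resolution
#' than the target-side cutoff, so the network is never trained to sharpen
#' (deblurring invites hallucination). Translations are in voxels, noise
#' amplitudes in density units of the corpus.
#'
#' @param res_range resolution cutoff range (Angstrom) for the target filter.
#' @param aniso_max maximum per-axis anisotropy factor on sigma (>= 1).
#' @param trans_max maximum |translation| per axis, voxels.
#' @param noise_amp_range colored-noise amplitude range.
#' @param noise_kind `"lorentzian"` (power falling with shell) or `"white"`.
#' @param noise_s0_frac knee shell of the lorentzian spectrum as a fraction
#'   of n.
#' @param r_max recycling counts are drawn uniformly from `{0, ..., r_max}`.
#' @param patch_edge crop edge, voxels.
#' @param lowpass_fill_resolution resolution (Angstrom) of the low-pass fill
#'   `h(.)` used outside the mask.
#' @export
augmentation_policy <- function(res_range = c(4.5, 15), aniso_max = 1.5,
                                trans_max = 2, noise_amp_range = c(0.3, 1.5),
                                noise_kind = c("lorentzian", "white"),
                                noise_s0_frac = 1 / 8, r_max = 5L,
                                patch_edge = 64L, lowpass_fill_resolution = 15) {
  noise_kind <- match.arg(noise_kind)
  if (diff(res_range) < 0 || res_range[1] <= 0) stop("invalid res_range")
  if (aniso_max < 1) stop("aniso_max must be >= 1")
  if (r_max < 0L || r_max > 5L) stop("r_max must be in 0..5")
  structure(list(res_range = res_range, aniso_max = aniso_max,
                 trans_max = trans_max, noise_amp_range = noise_amp_range,
                 noise_kind = noise_kind,
                 noise_s0_frac = noise_s0_frac, r_max = as.integer(r_max),
                 patch_edge = as.integer(patch_edge),
                 lowpass_fill_resolution = lowpass_fill_resolution),
            class = "blush_aug_policy")
}

#' Draw a random augmentation specification
#'
#' Deterministic under a fixed seed. Draws the filter pair (with
#' `resolution(C) >= resolution(Cbar)` in Angstrom, i.e. the input is never
#' sharpened relative to the target), a uniform rotation, a translation, a
#' noise spectrum and amplitude, the recycle count `r`, and a crop corner for
#' which the transformed crop stays inside the volume.
#'
#' @param seed integer seed.
#' @param policy an [augmentation_policy()].
#' @param n grid edge of the pair's volumes.
#' @param voxel_size voxel size of the pair's volumes (Angstrom).
#' @return A `blush_aug_spec` with fields `C`, `C_bar`, `A`, `noise`,
#'   `noise_amp`, `noise_seeds`, `crop_corner`, `r`, `patch_edge`,
#'   `lowpass_fill_resolution`.
#' @export
sample_spec <- function(seed = NULL, policy = augmentation_policy(), n, voxel_size) {
  with_seed(seed, {
    e <- policy$patch_edge
    if (e > n) stop("patch_edge exceeds the volume edge")
    res_bar <- runif(1, policy$res_range[1], policy$res_range[2])
    res_in <- runif(1, res_bar, policy$res_range[2])  # blur input at least as much
    aniso_in <- runif(3, 1, policy$aniso_max)
    aniso_bar <- runif(3, 1, policy$aniso_max)
    C <- gaussian_covariance(res_in, aniso_in, random_rotation())
    C_bar <- gaussian_covariance(res_bar, aniso_bar, random_rotation())
    A <- affine_transform(random_rotation(),
                          runif(3, -policy$trans_max, policy$trans_max))
    amp <- runif(1, policy$noise_amp_range[1], policy$noise_amp_range[2])
    spec <- if ((policy$noise_kind %||% "lorentzian") == "white")
      noise_spectrum(rep(amp, n / 2 + 1))
    else lorentzian_spectrum(n, s0 = policy$noise_s0_frac * n, amplitude = amp)
    r <- sample.int(policy$r_max + 1L, 1L) - 1L
    noise_seeds <- sample.int(2147483646L, 2L)
    corner <- draw_valid_corner(n, e, A)
    structure(list(C = C, C_bar = C_bar, res_in = res_in, res_bar = res_bar,
                   A = A, noise = spec, noise_amp = amp,
                   noise_seeds = noise_seeds, crop_corner = corner, r = r,
                   patch_edge = e,
                   lowpass_fill_resolution = policy$lowpass_fill_resolution),
              class = "blush_aug_spec")
  })
}

# Sample a crop corner whose 8 cube corners map inside the source grid;
# falls back to the centered corner (feasible whenever any corner is) if
# uniform draws keep landing outside under an adverse rotation.
draw_valid_corner <- function(n, e, A, tries = 50L) {
  corner_ok <- function(corner) {
    pts <- as.matrix(expand.grid(x = c(corner[1], corner[1] + e - 1),
                                 y = c(corner[2], corner[2] + e - 1),
                                 z = c(corner[3], corner[3] + e - 1)))
    q <- affine_source_coords(pts, A, n)
    all(q >= 1 & q <= n)
  }
  for (i in seq_len(tries)) {
    corner <- if (n == e) c(1, 1, 1) else floor(runif(3, 1, n - e + 1 + 1 - 1e-9))
    if (corner_ok(corner)) return(as.integer(corner))
  }
  centered <- rep(floor((n - e) / 2) + 1, 3)
  if (corner_ok(centered)) return(as.integer(centered))
  stop("could not place a crop inside the transformed volume (patch too large for this grid?)")
}

#' Build the input patch y of a training example
#'
#' Adds colored noise to the *other* half (`x^(1-k)`), then applies H with the
#' input-side filter `C` and the shared transform/crop. The noise stream is
#' indexed by the half it is added to, so input and target noise are
#' independent.
#'
#' @param pair a [halfmap_pair()]. @param k half index, 0 or 1.
#' @param spec a `blush_aug_spec` from [sample_spec()].
#' @export
make_input_y <- function(pair, k, spec) {
  x_other <- if (k == 0) pair$x1 else pair$x0
  n <- vol_edge(x_other)
  amp_zero <- all(spec$noise$amplitude == 0)
  noisy <- if (amp_zero) x_other else {
    e <- make_colored_noise(n, spec$noise, seed = spec$noise_seeds[(1 - k) + 1],
                            voxel_size = x_other$voxel_size)
    with_grid(x_other, vol_grid(x_other) + vol_grid(e))
  }
  apply_H(noisy, spec$C, spec$A, spec$crop_corner, spec$patch_edge)
}

#' Build the target patch ybar of a training example
#'
#' Blends `x^(k)` inside the mask with its low-pass filtered version outside
#' (so disordered regions keep plausible low-frequency density rather than
#' being zeroed), then applies H with the target-side filter `Cbar` and the
#' same transform and crop as the input side. An absent mask is treated as all
#' ones.
#'
#' @inheritParams make_input_y
#' @export
make_target_ybar <- function(pair, k, spec) {
  x_k <- if (k == 0) pair$x0 else pair$x1
  if (is.null(pair$mask)) {
    blended <- x_k
  } else {
    m <- vol_grid(pair$mask)
    lp <- lowpass_to_resolution(x_k, spec$lowpass_fill_resolution)
    blended <- with_grid(x_k, vol_grid(x_k) * m + vol_grid(lp) * (1 - m))
  }
  apply_H(blended, spec$C_bar, spec$A, spec$crop_corner, spec$patch_edge)
}

#' Build one training example from a half-map pair
#'
#' Draws one augmentation spec and constructs the (input, target) patch pair
#' for target half `k`; both `k = 0` and `k = 1` examples can be built from
#' one pair (the two passes of a sample). Zero-variance crops are re-drawn up
#' to `retries` times.
#'
#' @param pair a [halfmap_pair()]. @param k target half index (0 or 1).
#' @param seed integer seed. @param policy an [augmentation_policy()].
#' @param retries redraw attempts for degenerate crops.
#' @return A `blush_training_example`: `y`, `ybar` (standardized patch
#'   arrays), `r`, `id`.
#' @export
build_example <- function(pair, k, seed = NULL, policy = augmentation_policy(),
                          retries = 10L) {
  n <- vol_edge(pair$x0)
  vs <- pair$x0$voxel_size
  for (i in seq_len(retries)) {
    s <- derive_seed(seed, i - 1) %||% NULL
    res <- tryCatch({
      spec <- sample_spec(s, policy, n, vs)
      list(y = make_input_y(pair, k, spec),
           ybar = make_target_ybar(pair, k, spec), spec = spec)
    }, blushr_zero_variance = function(e) NULL)
    if (!is.null(res))
      return(structure(list(y = res$y, ybar = res$ybar, r = res$spec$r,
                            id = paste0(pair$id, "_k", k)),
                       class = "blush_training_example"))
  }
  stop("failed to draw a non-degenerate training example after ", retries, " tries")
}
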