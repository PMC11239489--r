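# Toy regularized-likelihood refinement: exhaustive projection matching over a
# coarse orientation grid (hard assignment), direct-Fourier backprojection by
# central-slice insertion with per-Fourier-voxel weight normalization, and the
# reference-update rule under test: either per-shell Wiener weighting
# (baseline) or denoised references guarded by spectral trailing.

#' Rotation matrix from ZYZ Euler angles
#'
#' `R = Rz(alpha) Ry(beta) Rz(gamma)`, angles in radians.
#'
#' @param alpha,beta,gamma Euler angles (radians).
#' @export
euler_to_matrix <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Quasi-uniform orientation search grid
#'
#' Viewing directions from a Fibonacci sphere combined with `n_psi` in-plane
#' angles; deterministic.
#'
#' @param n_dir number of viewing directions.
#' @param n_psi in-plane rotations per direction.
#' @return Matrix `(n_dir * n_psi) x 3` of ZYZ Euler angles (radians).
#' @export
make_orientation_grid <- function(n_dir = 20L, n_psi = 4L) {
  i <- seq_len(n_dir) - 0.5
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  cosb <- 1 - 2 * i / n_dir
  beta <- acos(pmin(pmax(cosb, -1), 1))
  alpha <- phi %% (2 * pi)
  psi <- seq(0, 2 * pi, length.out = n_psi + 1L)[seq_len(n_psi)]
  out <- as.matrix(expand.grid(gamma = psi, dir = seq_len(n_dir)))
  cbind(alpha = alpha[out[, "dir"]], beta = beta[out[, "dir"]], gamma = out[, "gamma"])
}

#' Particle dataset
#'
#' A stack of 2D projection images with per-particle orientation metadata and
#' a half-set split.
#'
#' @param images array `(n, n, P)`.
#' @param eulers `P x 3` ZYZ Euler angles (radians) currently assigned.
#' @param shifts `P x 2` in-plane shifts in Angstrom (zero in the toy model).
#' @param half integer vector of 0/1 half-set labels; both sets must be
#'   nonempty.
#' @param pixel_size Angstrom per pixel.
#' @param snr optional per-image signal-to-noise annotation.
#' @param true_index optional ground-truth orientation grid index.
#' @export
particle_dataset <- function(images, eulers, shifts = NULL, half,
                             pixel_size, snr = NA_real_, true_index = NULL) {
  P <- dim(images)[3]
  if (nrow(eulers) != P) stop("eulers must have one row per particle")
  half <- as.integer(half)
  if (length(half) != P || !all(half %in% c(0L, 1L))) stop("half labels must be 0/1 per particle")
  if (!any(half == 0L) || !any(half == 1L)) stop("both half-sets must be nonempty")
  structure(list(images = images, eulers = eulers,
                 shifts = shifts %||% matrix(0, P, 2), half = half,
                 pixel_size = pixel_size, snr = snr, true_index = true_index),
            class = "blush_particles")
}

# ---- central-slice projection and backprojection ----------------------------

# Fourier oversampling factor for gridding: the volume is embedded at the
# center of the (os*n)-cube and circularly shifted so the object center sits
# at the origin of the padded grid (support in [-n/2, n/2) mod os*n). The
# padded transform is then slowly varying -- accurate to interpolate with a
# trilinear kernel -- and F_pad(os*k) = F(k) * (-1)^{sum(k)} for any integer
# oversampling factor.
.blush_os <- 3L

pad_centered_origin <- function(g, os = .blush_os) {
  n <- dim(g)[1]
  m <- os * n
  pc <- array(0, rep(m, 3))
  lo <- (m - n) / 2 + 1L
  pc[lo:(lo + n - 1L), lo:(lo + n - 1L), lo:(lo + n - 1L)] <- g
  idx <- ((0:(m - 1) + (lo - 1L) + n / 2) %% m) + 1L
  pc[idx, idx, idx]
}

# complex trilinear sample of the oversampled FFT cube at real-valued
# signed frequencies q in ORIGINAL grid units (m x 3); frequencies outside
# the Nyquist ball return 0
fourier_slice_sample <- function(FV, q, n_orig) {
  n <- dim(FV)[1]
  r <- sqrt(rowSums(q^2))
  q <- .blush_os * q
  ok <- r <= n_orig / 2
  val <- complex(length.out = nrow(q))
  if (any(ok)) {
    qq <- q[ok, , drop = FALSE]
    f0 <- floor(qq)
    fr <- qq - f0
    acc <- complex(length.out = nrow(qq))
    for (o in 0:7) {
      d <- c(o %% 2, (o %/% 2) %% 2, o %/% 4)
      w <- ((if (d[1] == 1) fr[, 1] else 1 - fr[, 1]) *
            (if (d[2] == 1) fr[, 2] else 1 - fr[, 2]) *
            (if (d[3] == 1) fr[, 3] else 1 - fr[, 3]))
      ii <- ((f0[, 1] + d[1]) %% n) + 1L
      jj <- ((f0[, 2] + d[2]) %% n) + 1L
      kk <- ((f0[, 3] + d[3]) %% n) + 1L
      acc <- acc + w * FV[cbind(ii, jj, kk)]
    }
    val[ok] <- acc
  }
  val
}

# 2D signed frequency grid (n^2 x 2) for an n x n image
freq_grid2 <- function(n) {
  f <- freq_index(n)
  as.matrix(expand.grid(fx = f, fy = f))
}

#' Project a volume along an orientation (central-slice theorem)
#'
#' Rotates the volume by the orientation matrix and sums along z, implemented
#' by sampling the central slice `F(R^T (kx, ky, 0))` of the 3D Fourier
#' transform with complex trilinear interpolation.
#'
#' @param vol a [volume()]. @param rot 3x3 rotation matrix.
#' @param FV optionally, the precomputed oversampled transform from
#'   [project_fft()] to reuse across calls.
#' @return `n x n` image (density summed along the projection axis).
#' @export
project_volume <- function(vol, rot, FV = NULL) {
  g <- vol_grid(vol)
  n <- dim(g)[1]
  if (is.null(FV)) FV <- project_fft(vol)
  k2 <- freq_grid2(n)
  q <- cbind(k2, 0) %*% rot   # rows: R^T k
  sl <- fourier_slice_sample(FV, q, n) * exp(-1i * pi * rowSums(q))
  Re(fft(matrix(sl, n, n), inverse = TRUE)) / n^2
}

#' Precompute the oversampled Fourier transform used by [project_volume()]
#' @param vol a [volume()] or 3D array.
#' @export
project_fft <- function(vol) {
  fft(pad_centered_origin(vol_grid(vol)))
}

#' Backproject a half-set into a volume
#'
#' Direct-Fourier inversion: the 2D Fourier transform of every image in the
#' half-set is spread into the 3D Fourier grid at its central slice with
#' trilinear weights; accumulated values are divided by the accumulated
#' weights per Fourier voxel (zero where nothing was inserted). This is the
#' adjoint-consistent inverse of [project_volume()].
#'
#' @param data a [particle_dataset()]. @param half 0 or 1.
#' @param eulers optional `P x 3` Euler assignments overriding `data$eulers`.
#' @return A [volume()].
#' @export
backproject_halfset <- function(data, half, eulers = NULL) {
  sel <- which(data$half == half)
  if (length(sel) == 0) stop("half-set ", half, " is empty")
  eulers <- eulers %||% data$eulers
  n <- dim(data$images)[1]
  N <- .blush_os * n                # oversampled Fourier grid
  k2 <- freq_grid2(n)
  accR <- numeric(N^3); accI <- numeric(N^3); wacc <- numeric(N^3)
  for (p in sel) {
    P2 <- fft(data$images[, , p])
    rot <- euler_to_matrix(eulers[p, 1], eulers[p, 2], eulers[p, 3])
    q <- cbind(k2, 0) %*% rot
    r <- sqrt(rowSums(q^2))
    ok <- r <= n / 2
    qo <- q[ok, , drop = FALSE]
    qq <- .blush_os * qo             # oversampled coordinates
    # insert values of the origin-centered transform: F_shift(q) = F(q) e^{i pi sum(q)}
    v <- as.vector(P2)[ok] * exp(1i * pi * rowSums(qo))
    f0 <- floor(qq)
    fr <- qq - f0
    for (o in 0:7) {
      d <- c(o %% 2, (o %/% 2) %% 2, o %/% 4)
      w <- ((if (d[1] == 1) fr[, 1] else 1 - fr[, 1]) *
            (if (d[2] == 1) fr[, 2] else 1 - fr[, 2]) *
            (if (d[3] == 1) fr[, 3] else 1 - fr[, 3]))
      idx <- (((f0[, 1] + d[1]) %% N)) + N * ((f0[, 2] + d[2]) %% N) +
        N^2 * ((f0[, 3] + d[3]) %% N) + 1
      sw <- rowsum(cbind(w * Re(v), w * Im(v), w), idx, reorder = FALSE)
      ui <- as.integer(rownames(sw))
      accR[ui] <- accR[ui] + sw[, 1]
      accI[ui] <- accI[ui] + sw[, 2]
      wacc[ui] <- wacc[ui] + sw[, 3]
    }
  }
  good <- wacc > 1e-8
  GR <- ifelse(good, accR / pmax(wacc, 1e-8), 0)
  GI <- ifelse(good, accI / pmax(wacc, 1e-8), 0)
  # original-grid transform: F(k) = F_shift(k) * (-1)^{sum(k)}, F_shift(k) = F_pad(2k)
  ex <- (.blush_os * freq_index(n)) %% N + 1L
  GR <- array(GR, rep(N, 3))[ex, ex, ex]
  GI <- array(GI, rep(N, 3))[ex, ex, ex]
  sgn <- (-1)^abs(freq_index(n))
  sg3 <- outer(outer(sgn, sgn), sgn)
  FV <- array(complex(real = GR, imaginary = GI), rep(n, 3)) * sg3
  volume(Re(fft(FV, inverse = TRUE)) / n^3, data$pixel_size)
}

#' Align particles to half-set references by projection matching
#'
#' Exhaustive search over an orientation grid: each particle receives the grid
#' orientation whose reference projection (from the reference of its own
#' half-set) maximizes the normalized cross-correlation with its image. Ties
#' (including all-constant references) resolve to the lowest grid index.
#'
#' @param data a [particle_dataset()].
#' @param ref0,ref1 reference [volume()]s for half-sets 0 and 1.
#' @param grid_eulers `G x 3` matrix of ZYZ Euler angles.
#' @return `list(index, eulers, cc)`: per-particle grid index, Euler angles
#'   and best correlation.
#' @export
align_particles <- function(data, ref0, ref1, grid_eulers) {
  n <- dim(data$images)[1]
  P <- dim(data$images)[3]
  G <- nrow(grid_eulers)
  imgm <- matrix(data$images, n * n, P)
  imgc <- sweep(imgm, 2, colMeans(imgm))
  inorm <- sqrt(colSums(imgc^2))
  best_cc <- rep(-Inf, P)
  best_g <- rep(1L, P)
  for (h in 0:1) {
    ref <- if (h == 0) ref0 else ref1
    if (!all(is.finite(vol_grid(ref)))) stop("non-finite reference for half-set ", h)
    FV <- project_fft(ref)
    sel <- which(data$half == h)
    for (g in seq_len(G)) {
      rot <- euler_to_matrix(grid_eulers[g, 1], grid_eulers[g, 2], grid_eulers[g, 3])
      pr <- as.vector(project_volume(ref, rot, FV = FV))
      pr <- pr - mean(pr)
      pn <- sqrt(sum(pr^2))
      cc <- if (pn < 1e-12) rep(0, length(sel))
            else as.vector(crossprod(imgc[, sel, drop = FALSE], pr)) /
                 (pmax(inorm[sel], 1e-12) * pn)
      upd <- cc > best_cc[sel] + 1e-12
      best_cc[sel[upd]] <- cc[upd]
      best_g[sel[upd]] <- g
    }
  }
  list(index = best_g, eulers = grid_eulers[best_g, , drop = FALSE], cc = best_cc)
}

# ---- spectral trailing and Wiener filtering ---------------------------------

#' Spectral-trailing state
#'
#' Bundles the FSC-0.143 cutoff shell `rho`, the trailing shell `rho - 2`
#' (clamped to `[1, n/2]`), and the shell of the denoiser's native Nyquist
#' limit (3 Angstrom for a denoiser trained at 1.5 Angstrom voxels) on the
#' current grid.
#'
#' @param rho cutoff shell from the solvent-corrected FSC.
#' @param n grid edge. @param voxel_size Angstrom per voxel.
#' @param denoiser_nyquist_A denoiser resolution limit in Angstrom.
#' @export
trailing_state <- function(rho, n, voxel_size, denoiser_nyquist_A = 3) {
  rho <- as.integer(rho)
  trail <- max(1L, min(rho - 2L, as.integer(n / 2)))
  nyq <- resolution_to_shell(denoiser_nyquist_A, n, voxel_size)
  structure(list(rho = rho, trail_shell = trail, nyquist_shell = nyq,
                 n = as.integer(n)),
            class = "blush_trailing_state")
}

#' Trailing filter: splice denoised and fallback maps in Fourier shells
#'
#' Shells at or below the trailing cutoff take the denoised map's Fourier
#' components. Above it: if `rho` is within the denoiser's Nyquist limit, all
#' higher shells are set to zero (hard cutoff); if `rho` exceeds that limit,
#' shells above the Nyquist shell are populated from the fallback
#' (standard-regularized) map, with any gap between the trailing cutoff and
#' the Nyquist shell zeroed. The denoised content below the cutoff is passed
#' through bit-unchanged.
#'
#' @param denoised,fallback [volume()]s of identical shape.
#' @param ts a [trailing_state()].
#' @export
trailing_filter <- function(denoised, fallback, ts) {
  stopifnot_same_shape(denoised, fallback)
  n <- vol_edge(denoised)
  s <- shell_index(n)                 # 1-based shell bins
  FD <- fft(vol_grid(denoised))
  use_fallback <- ts$rho > ts$nyquist_shell
  lim <- min(ts$trail_shell, if (use_fallback) ts$nyquist_shell else ts$trail_shell)
  FO <- array(0 + 0i, rep(n, 3))
  keep <- s <= lim + 1L
  FO[keep] <- FD[keep]
  if (use_fallback) {
    FB <- fft(vol_grid(fallback))
    hi <- s > ts$nyquist_shell + 1L
    FO[hi] <- FB[hi]
  }
  with_grid(denoised, Re(fft(FO, inverse = TRUE)) / n^3)
}

# per-shell Wiener weight from a half-map FSC, clamped to [0, 1]
wiener_gain <- function(fsc) pmin(pmax(2 * fsc$values / (1 + fsc$values), 0), 1)

#' Final-map Wiener filter
#'
#' Averages the two half-maps and applies the gold-standard per-shell signal
#' weight `2 FSC / (1 + FSC)`, clamped to `[0, 1]`.
#'
#' @param half0,half1 final half-maps. @param fsc their `blush_fsc`.
#' @export
wiener_filter_final <- function(half0, half1, fsc) {
  stopifnot_same_shape(half0, half1)
  avg <- with_grid(half0, (vol_grid(half0) + vol_grid(half1)) / 2)
  apply_shell_filter(avg, wiener_gain(fsc))
}

#' Refinement configuration
#'
#' @param iterations number of expectation-maximization iterations (>= 1).
#' @param grid_eulers orientation search grid (`G x 3` ZYZ Euler angles).
#' @param mode `"blush"` (denoised references with spectral trailing) or
#'   `"baseline"` (per-shell Wiener-weighted references).
#' @param initial_reference [volume()] used as both half-set references at the
#'   first iteration (typically a low-pass filtered initial model).
#' @param mask optional solvent mask for the corrected FSC.
#' @param rand_shell phase-randomization shell for the solvent-corrected FSC.
#' @param denoiser_nyquist_A denoiser resolution limit (Angstrom).
#' @param patch_edge,overlap patched-inference settings for the denoiser.
#' @param spectral_trailing if `FALSE`, denoised references are used full-band
#'   without the trailing filter (the ablation of the safeguard); ignored in
#'   baseline mode.
#' @param denoise_input what the denoiser sees in blush mode: the
#'   `"filtered"` (Wiener-weighted, resolution-limited) half-map from the
#'   regularized-likelihood update — as in the classification variant of the
#'   method — or the `"raw"` backprojected half-map.
#' @param keep_refs if `TRUE`, per-iteration references and orientation
#'   assignments are kept in the result (for diagnostics; memory scales with
#'   iterations).
#' @param seed integer seed.
#' @export
refinement_config <- function(iterations, grid_eulers,
                              mode = c("blush", "baseline"),
                              initial_reference, mask = NULL, rand_shell = NULL,
                              denoiser_nyquist_A = 3, patch_edge = NULL,
                              overlap = NULL, spectral_trailing = TRUE,
                              denoise_input = c("filtered", "raw"),
                              keep_refs = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  denoise_input <- match.arg(denoise_input)
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(iterations = as.integer(iterations), grid_eulers = grid_eulers,
                 mode = mode, initial_reference = initial_reference, mask = mask,
                 rand_shell = rand_shell, denoiser_nyquist_A = denoiser_nyquist_A,
                 patch_edge = patch_edge, overlap = overlap,
                 spectral_trailing = isTRUE(spectral_trailing),
                 denoise_input = denoise_input,
                 keep_refs = isTRUE(keep_refs), seed = as.integer(seed)),
            class = "blush_refine_config")
}

# denoise at the model's training voxel size, rescaling there and back when
# the refinement grid differs by more than 5%
denoise_at_scale <- function(model, v, cfg) {
  tv <- model$config$voxel_size
  if (abs(v$voxel_size - tv) / tv <= 0.05)
    return(denoise_volume(model, v, cfg$patch_edge, cfg$overlap))
  vr <- rescale_voxel_size(v, tv)
  dr <- denoise_volume(model, vr, cfg$patch_edge, cfg$overlap)
  rescale_voxel_size(dr, v$voxel_size)
}

#' Iterative refinement with optional denoiser regularization
#'
#' Per iteration: align each half-set against its own reference, backproject
#' each half, compute the solvent-corrected half-map FSC and the cutoff shell
#' `rho`. In `"blush"` mode the new references are the denoised half-maps
#' spliced by the trailing filter with the Wiener-weighted raw half-map as the
#' above-Nyquist fallback; in `"baseline"` mode they are the Wiener-weighted
#' half-maps. The final iteration never applies the denoiser: the returned map
#' is the Wiener-filtered average of the last half-maps.
#'
#' @param data a [particle_dataset()].
#' @param model a `blush_denoiser` (required for `mode = "blush"`).
#' @param cfg a [refinement_config()].
#' @return `list(map, half0, half1, trace)`; `trace` has one row per
#'   iteration (`iter`, `rho`, `trail_shell`) plus per-iteration FSC curves in
#'   `attr(trace, "fsc")` and the last orientation assignments in
#'   `assignments`.
#' @export
refine <- function(data, model = NULL, cfg) {
  if (cfg$mode == "blush" && is.null(model)) stop("mode = 'blush' requires a model")
  n <- dim(data$images)[1]
  vs <- data$pixel_size
  rand_shell <- cfg$rand_shell %||% max(2L, as.integer(n / 4))
  ref0 <- ref1 <- cfg$initial_reference
  trace <- data.frame(iter = integer(0), rho = integer(0), trail_shell = integer(0))
  fsc_list <- list()
  assign_last <- NULL
  ref_list <- list()
  assign_list <- list()
  for (it in seq_len(cfg$iterations)) {
    al <- align_particles(data, ref0, ref1, cfg$grid_eulers)
    assign_last <- al
    if (cfg$keep_refs) assign_list[[it]] <- al$index
    h0 <- backproject_halfset(data, 0L, eulers = al$eulers)
    h1 <- backproject_halfset(data, 1L, eulers = al$eulers)
    if (!all(is.finite(vol_grid(h0))) || !all(is.finite(vol_grid(h1))))
      stop("non-finite reference at iteration ", it)
    fsc <- solvent_corrected_fsc(h0, h1, cfg$mask, rand_shell,
                                 seed = derive_seed(cfg$seed, it))
    rho <- estimate_rho(fsc)
    ts <- trailing_state(rho, n, vs, cfg$denoiser_nyquist_A)
    trace <- rbind(trace, data.frame(iter = it, rho = rho, trail_shell = ts$trail_shell))
    fsc_list[[it]] <- fsc
    if (it == cfg$iterations) {
      final <- wiener_filter_final(h0, h1, fsc)
      attr(trace, "fsc") <- fsc_list
      return(list(map = final, half0 = h0, half1 = h1, trace = trace,
                  assignments = assign_last,
                  refs = if (cfg$keep_refs) ref_list else NULL,
                  assignment_history = if (cfg$keep_refs) assign_list else NULL))
    }
    # per-shell Wiener weight from the half-map FSC; references additionally
    # low-passed at the current resolution estimate, the standard safeguard of
    # gold-standard refinement against aligning to noise
    gain <- wiener_gain(fsc) * make_lowpass(max(rho, 1L), n)$gain
    fb0 <- apply_shell_filter(h0, gain)
    fb1 <- apply_shell_filter(h1, gain)
    if (cfg$mode == "baseline") {
      ref0 <- fb0; ref1 <- fb1
    } else {
      din0 <- if (cfg$denoise_input == "filtered") fb0 else h0
      din1 <- if (cfg$denoise_input == "filtered") fb1 else h1
      d0 <- denoise_at_scale(model, din0, cfg)
      d1 <- denoise_at_scale(model, din1, cfg)
      if (cfg$spectral_trailing) {
        ref0 <- trailing_filter(d0, fb0, ts)
        ref1 <- trailing_filter(d1, fb1, ts)
      } else {
        ref0 <- d0
        ref1 <- d1
      }
    }
    if (cfg$keep_refs) ref_list[[it]] <- list(ref0 = ref0, ref1 = ref1)
  }
}

#' Per-class denoiser hook for 3D classification
#'
#' In classification mode the filtered map from the regularized-likelihood
#' update is passed through the denoiser directly — no trailing filter, no
#' extra low-pass — and, unlike refinement, the hook is applied at the final
#' iteration too.
#'
#' @param filtered_class_map a [volume()]. @param model a `blush_denoiser`.
#' @param cfg optional [refinement_config()] for patching parameters.
#' @export
classify_denoise_hook <- function(filtered_class_map, model, cfg = NULL) {
  if (!all(is.finite(vol_grid(filtered_class_map)))) stop("non-finite class map")
  pe <- if (!is.null(cfg)) cfg$patch_edge else NULL
  ov <- if (!is.null(cfg)) cfg$overlap else NULL
  denoise_volume(model, filtered_class_map, pe, ov)
}
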