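# Fourier-shell machinery. All operations use the unnormalized DFT from
# stats::fft on the full complex cube; signed integer frequencies run over
# [-n/2, n/2 - 1] per axis and a Fourier voxel belongs to the shell
# s = round(|f|), one voxel wide, so shell s corresponds to resolution
# n * voxel_size / s Angstrom. Corner voxels with s > n/2 lie beyond Nyquist:
# they are excluded from FSC curves and handled by the last shell's gain in
# shell filters.

.shell_cache <- new.env(parent = emptyenv())

# signed frequency index per axis position (1-based array index)
freq_index <- function(n) {
  i <- 0:(n - 1)
  ifelse(i < n / 2, i, i - n)
}

# cached 1-based shell bin per Fourier voxel (values 1 .. max shell + 1)
shell_index <- function(n) {
  key <- as.character(n)
  if (!is.null(.shell_cache[[key]])) return(.shell_cache[[key]])
  f <- freq_index(n)
  f2 <- f^2
  r <- sqrt(outer(outer(f2, f2, "+"), f2, "+"))
  s <- array(as.integer(round(r)) + 1L, rep(n, 3))
  .shell_cache[[key]] <- s
  s
}

# per-shell sums of x over shells 1..n/2 (+1 for DC); x numeric vector over voxels
shell_sums <- function(x, n) {
  s <- as.vector(shell_index(n))
  nb <- n / 2 + 1
  keep <- s <= nb
  as.vector(rowsum(x[keep], s[keep], reorder = TRUE))
}

shell_counts <- function(n) {
  key <- paste0("cnt", n)
  if (!is.null(.shell_cache[[key]])) return(.shell_cache[[key]])
  s <- as.vector(shell_index(n))
  nb <- n / 2 + 1
  cnt <- tabulate(s[s <= nb], nbins = nb)
  .shell_cache[[key]] <- cnt
  cnt
}

fsc_curve <- function(values, n, voxel_size) {
  structure(list(values = as.numeric(values), n = as.integer(n),
                 voxel_size = as.numeric(voxel_size)),
            class = "blush_fsc")
}

#' @export
print.blush_fsc <- function(x, ...) {
  cat(sprintf("<FSC curve, %d shells, n = %d, voxel %.3g A>\n",
              length(x$values), x$n, x$voxel_size))
  invisible(x)
}

#' Shell resolution in Angstrom
#'
#' Converts between integer Fourier shell index and resolution on an `n`-voxel
#' grid: shell `s` corresponds to `n * voxel_size / s` Angstrom. The
#' resolution-to-shell direction rounds down, so a filter built from a stated
#' resolution never passes frequencies beyond it.
#'
#' @param s shell index (>= 1).
#' @param resolution resolution in Angstrom.
#' @param n grid edge. @param voxel_size Angstrom per voxel.
#' @export
shell_to_resolution <- function(s, n, voxel_size) n * voxel_size / s

#' @rdname shell_to_resolution
#' @export
resolution_to_shell <- function(resolution, n, voxel_size) {
  s <- floor(n * voxel_size / resolution)
  as.integer(max(1L, min(s, n %/% 2)))
}

#' Fourier shell correlation between two volumes
#'
#' For each integer shell `s` the correlation is
#' `Re(sum(A * Conj(B))) / sqrt(sum(|A|^2) * sum(|B|^2))` over the Fourier
#' voxels with `round(|f|) = s`. Empty or zero-power shells return 0.
#'
#' @param a,b volumes (or 3D arrays) of identical shape and voxel size.
#' @return A `blush_fsc` with `n/2 + 1` values for shells `0..n/2`.
#' @export
compute_fsc <- function(a, b) {
  stopifnot_same_shape(a, b)
  ga <- vol_grid(a); gb <- vol_grid(b)
  n <- dim(ga)[1]
  A <- fft(ga); B <- fft(gb)
  num <- shell_sums(Re(A * Conj(B)), n)
  pa <- shell_sums(Re(A * Conj(A)), n)
  pb <- shell_sums(Re(B * Conj(B)), n)
  den <- sqrt(pa * pb)
  vals <- ifelse(den > 0, num / den, 0)
  vs <- if (is_volume(a)) a$voxel_size else 1
  fsc_curve(vals, n, vs)
}

#' Randomize Fourier phases beyond a shell
#'
#' Replaces the phases of all Fourier voxels at shells `>= shell_start` with
#' the (Hermitian-symmetric) phases of a white Gaussian field, exactly
#' preserving amplitudes; shells below `shell_start` are untouched. Used by the
#' solvent-corrected FSC and by overfitting tests.
#'
#' @param v a [volume()] or 3D array.
#' @param shell_start first randomized shell, `1 <= shell_start <= n/2`.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @export
randomize_phases <- function(v, shell_start, seed = NULL) {
  g <- vol_grid(v)
  n <- dim(g)[1]
  if (shell_start < 1 || shell_start > n / 2) stop("need 1 <= shell_start <= n/2")
  FV <- fft(g)
  W <- fft(with_seed(seed, array(rnorm(n^3), rep(n, 3))))
  mw <- Mod(W)
  ph <- ifelse(mw > 1e-300, W / mw, 1 + 0i)
  sel <- shell_index(n) >= shell_start + 1L   # shell bins are 1-based
  FV[sel] <- Mod(FV[sel]) * ph[sel]
  out <- Re(fft(FV, inverse = TRUE)) / n^3
  with_grid(v, out)
}

#' Solvent-corrected FSC via phase randomization
#'
#' Computes the masked FSC and subtracts the spurious correlation induced by
#' the mask, estimated by recomputing the masked FSC after phase-randomizing
#' both maps beyond `rand_shell`:
#' `corrected = (FSC_t - FSC_n) / (1 - FSC_n)` for shells more than `margin`
#' above `rand_shell`, and the plain masked FSC below. If the noise FSC
#' reaches 1 at some shell the corrected value is clamped to 0 with a warning.
#'
#' @param a,b half-maps. @param mask volume with values in `[0, 1]`.
#' @param rand_shell shell beyond which phases are randomized.
#' @param n_rand number of randomization draws averaged for the noise FSC.
#' @param margin shells above `rand_shell` before the correction applies.
#' @param seed integer seed.
#' @export
solvent_corrected_fsc <- function(a, b, mask = NULL, rand_shell,
                                  n_rand = 1L, margin = 2L, seed = NULL) {
  stopifnot_same_shape(a, b)
  ga <- vol_grid(a); gb <- vol_grid(b)
  m <- if (is.null(mask)) 1 else vol_grid(mask)
  if (!is.numeric(m) || (length(m) > 1 && (min(m) < -1e-9 || max(m) > 1 + 1e-9)))
    stop("mask values must lie in [0, 1]")
  n <- dim(ga)[1]
  fsc_t <- compute_fsc(with_grid(a, ga * m), with_grid(b, gb * m))
  acc <- rep(0, n / 2 + 1)
  for (i in seq_len(n_rand)) {
    ra <- randomize_phases(ga, rand_shell, seed = derive_seed(seed, 2 * i))
    rb <- randomize_phases(gb, rand_shell, seed = derive_seed(seed, 2 * i + 1))
    acc <- acc + compute_fsc(ra * m, rb * m)$values
  }
  fsc_n <- acc / n_rand
  vals <- fsc_t$values
  corr_from <- rand_shell + margin   # shell index; bins are values' index - 1
  for (s in seq_along(vals)) {
    shell <- s - 1
    if (shell > corr_from) {
      if (fsc_n[s] >= 1 - 1e-12) {
        warning("noise FSC reached 1 at shell ", shell, "; corrected value clamped to 0")
        vals[s] <- 0
      } else {
        vals[s] <- (vals[s] - fsc_n[s]) / (1 - fsc_n[s])
      }
    }
  }
  fsc_curve(vals, n, fsc_t$voxel_size)
}

#' Resolution cutoff shell from an FSC curve
#'
#' First-crossing rule at the gold-standard 0.143 threshold: the estimate is
#' the largest shell `rho` such that the FSC is at or above the threshold at
#' every shell `1..rho`. If shell 1 is already below, `rho = 1`; if the curve
#' never drops below, `rho = n/2`.
#'
#' @param fsc a `blush_fsc`. @param threshold correlation threshold.
#' @return Integer shell index.
#' @export
estimate_rho <- function(fsc, threshold = 0.143) {
  v <- fsc$values[-1]           # shells 1..n/2
  below <- which(v < threshold)
  if (length(below) == 0) return(as.integer(fsc$n / 2))
  as.integer(max(1L, below[1] - 1L))
}

#' Construct a low-pass shell filter
#'
#' Gain 1 up to `cutoff_shell - edge_width`, raised-cosine ramp reaching 0 at
#' `cutoff_shell`, and 0 beyond. `edge_width = 0` gives a hard cutoff that
#' passes `cutoff_shell` itself and zeroes everything above it.
#'
#' @param cutoff_shell shell index of the cutoff.
#' @param n grid edge the filter applies to.
#' @param edge_width ramp width in shells (>= 0).
#' @return A `blush_shell_filter` with per-shell `gain` for shells `0..n/2`.
#' @export
make_lowpass <- function(cutoff_shell, n, edge_width = 0L) {
  if (cutoff_shell < 1 || cutoff_shell > n / 2) stop("need 1 <= cutoff_shell <= n/2")
  s <- 0:(n / 2)
  if (edge_width == 0) {
    gain <- as.numeric(s <= cutoff_shell)
  } else {
    gain <- rep(0, length(s))
    gain[s <= cutoff_shell - edge_width] <- 1
    ramp <- s > cutoff_shell - edge_width & s <= cutoff_shell
    gain[ramp] <- 0.5 * (1 + cos(pi * (s[ramp] - (cutoff_shell - edge_width)) / edge_width))
  }
  structure(list(gain = gain, n = as.integer(n)), class = "blush_shell_filter")
}

#' Apply a per-shell filter to a volume
#'
#' Multiplies each Fourier voxel by the gain of its shell; voxels beyond the
#' last tabulated shell (grid corners past Nyquist) use the last gain.
#'
#' @param v a [volume()] or 3D array. @param filt a `blush_shell_filter` or a
#'   bare numeric gain vector for shells `0..n/2`.
#' @export
apply_shell_filter <- function(v, filt) {
  g <- vol_grid(v)
  n <- dim(g)[1]
  gain <- if (inherits(filt, "blush_shell_filter")) filt$gain else as.numeric(filt)
  if (length(gain) != n / 2 + 1) stop("filter gain length must be n/2 + 1")
  if (any(!is.finite(gain)) || any(gain < 0)) stop("filter gains must be finite and >= 0")
  s <- shell_index(n)
  s[s > length(gain)] <- length(gain)
  FV <- fft(g) * array(gain[s], rep(n, 3))
  with_grid(v, Re(fft(FV, inverse = TRUE)) / n^3)
}

#' Low-pass filter a volume to a stated resolution
#'
#' Convenience wrapper: converts `resolution` to a shell (rounding down) and
#' applies a hard cutoff, the `h(.)` operation used to fill disordered regions
#' in target construction.
#'
#' @param v a [volume()]. @param resolution Angstrom. @param edge_width shells.
#' @export
lowpass_to_resolution <- function(v, resolution, edge_width = 0L) {
  n <- vol_edge(v)
  vs <- if (is_volume(v)) v$voxel_size else stop("need a blush_volume for resolution units")
  cutoff <- resolution_to_shell(resolution, n, vs)
  apply_shell_filter(v, make_lowpass(cutoff, n, edge_width))
}

#' Anisotropic Gaussian filter
#'
#' Multiplies the Fourier transform by `exp(-2 pi^2 k' C k)` with `k` in
#' cycles/Angstrom, i.e. real-space convolution with a Gaussian of covariance
#' `C` (squared lengths in Angstrom^2). `C = 0` is the identity.
#'
#' @param v a [volume()] or 3D array (then voxel size 1 is assumed).
#' @param C symmetric positive-semidefinite 3x3 matrix (Angstrom^2).
#' @export
anisotropic_gaussian_filter <- function(v, C) {
  C <- as.matrix(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8))) stop("C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("C must be positive semidefinite")
  g <- vol_grid(v)
  n <- dim(g)[1]
  vs <- if (is_volume(v)) v$voxel_size else 1
  k <- freq_index(n) / (n * vs)   # cycles/A
  q <- outer(outer(C[1, 1] * k^2, C[2, 2] * k^2, "+"), C[3, 3] * k^2, "+")
  if (C[1, 2] != 0) q <- q + outer(outer(2 * C[1, 2] * k, k, "*"), rep(1, n))
  if (C[1, 3] != 0) q <- q + outer(outer(2 * C[1, 3] * k, rep(1, n)), k)
  if (C[2, 3] != 0) q <- q + outer(outer(rep(1, n), 2 * C[2, 3] * k), k)
  FV <- fft(g) * exp(-2 * pi^2 * q)
  with_grid(v, Re(fft(FV, inverse = TRUE)) / n^3)
}

#' Isotropic Gaussian covariance from a resolution cutoff
#'
#' Maps a resolution cutoff `R` to the isotropic covariance whose Fourier gain
#' is 0.5 at spatial frequency `1/R`: `sigma^2 = R^2 log(2) / (2 pi^2)`.
#' Optional per-axis anisotropy factors scale the standard deviation along the
#' principal axes, and a rotation re-orients them.
#'
#' @param resolution cutoff in Angstrom (Inf gives `C = 0`).
#' @param aniso length-3 multiplicative factors on sigma per principal axis.
#' @param rotation 3x3 rotation applied to the principal axes.
#' @return 3x3 covariance matrix (Angstrom^2).
#' @export
gaussian_covariance <- function(resolution, aniso = c(1, 1, 1), rotation = diag(3)) {
  if (!is.finite(resolution)) return(matrix(0, 3, 3))
  s2 <- resolution^2 * log(2) / (2 * pi^2)
  rotation %*% diag(s2 * aniso^2) %*% t(rotation)
}

#' Noise spectrum
#'
#' Per-shell RMS Fourier amplitude (density units) for colored-noise
#' synthesis. [lorentzian_spectrum()] gives the package default
#' `amplitude / (1 + (s/s0)^2)`, mimicking the falling spectral SNR of
#' cryo-EM maps; a constant vector gives white noise.
#'
#' @param amplitude per-shell amplitudes, length `n/2 + 1`, all >= 0.
#' @export
noise_spectrum <- function(amplitude) {
  amplitude <- as.numeric(amplitude)
  if (any(amplitude < 0) || any(!is.finite(amplitude))) stop("amplitudes must be finite and >= 0")
  structure(list(amplitude = amplitude), class = "blush_noise_spectrum")
}

#' @param n grid edge. @param s0 knee shell. @param amplitude scale.
#' @rdname noise_spectrum
#' @export
lorentzian_spectrum <- function(n, s0 = n / 8, amplitude = 1) {
  s <- 0:(n / 2)
  noise_spectrum(amplitude / (1 + (s / s0)^2))
}

#' Synthesize colored Gaussian noise
#'
#' Returns a real Gaussian random field whose expected per-shell RMS Fourier
#' amplitude (`sqrt(E|F|^2 / n^3)` of the unnormalized DFT) equals the
#' requested spectrum; deterministic under a fixed seed.
#'
#' @param n grid edge. @param spectrum a [noise_spectrum()] of length `n/2+1`.
#' @param seed integer seed. @param voxel_size voxel size of the result.
#' @export
make_colored_noise <- function(n, spectrum, seed = NULL, voxel_size = 1) {
  amp <- if (inherits(spectrum, "blush_noise_spectrum")) spectrum$amplitude else as.numeric(spectrum)
  if (length(amp) != n / 2 + 1) stop("spectrum length must be n/2 + 1")
  w <- with_seed(seed, array(rnorm(n^3), rep(n, 3)))
  if (all(amp == 0)) return(volume(array(0, rep(n, 3)), voxel_size))
  s <- shell_index(n)
  s[s > length(amp)] <- length(amp)
  # E|fft(w)|^2 = n^3, so gain amp[s] gives per-shell RMS amplitude amp[s]
  FV <- fft(w) * array(amp[s], rep(n, 3))
  volume(Re(fft(FV, inverse = TRUE)) / n^3, voxel_size)
}

#' Per-shell power spectrum
#'
#' Mean `|F|^2 / n^3` per shell of the unnormalized DFT (so white noise of
#' unit variance has a flat spectrum of 1).
#'
#' @param v a [volume()] or 3D array.
#' @export
power_spectrum <- function(v) {
  g <- vol_grid(v)
  n <- dim(g)[1]
  p <- shell_sums(Mod(fft(g))^2, n) / shell_counts(n)
  p / n^3
}

#' Resample a volume to a different voxel size by Fourier cropping/padding
#'
#' Band-limits (or zero-pads) the Fourier transform so the grid spacing
#' changes without an interpolation kernel: the output edge is
#' `round(n * voxel_in / target)` rounded up to even, the physical extent is
#' preserved, and the stored voxel size is the effective spacing
#' `extent / n_out` (within one voxel of `target`). The DC component (mean
#' density) is preserved exactly.
#'
#' @param vol a [volume()]. @param target requested Angstrom per voxel.
#' @export
rescale_voxel_size <- function(vol, target) {
  if (!is_volume(vol)) stop("vol must be a blush_volume")
  if (target <= 0) stop("target voxel size must be > 0")
  n <- vol_edge(vol)
  extent <- n * vol$voxel_size
  m <- as.integer(round(extent / target))
  if (m %% 2L == 1L) m <- m + 1L
  if (m < 16L) stop("target voxel size would give an edge of ", m, " < 16 voxels")
  if (m == n) return(vol)
  FV <- fft(vol$grid)
  keep <- min(m, n)
  f <- freq_index(keep)
  src <- (f %% n) + 1L   # index of signed frequency f in the size-n FFT
  dst <- (f %% m) + 1L   # ... and in the size-m FFT
  FM <- array(0 + 0i, rep(m, 3))
  FM[dst, dst, dst] <- FV[src, src, src]
  # (m/n)^3 rescales DFT magnitudes so mean density is preserved exactly
  out <- Re(fft(FM, inverse = TRUE)) * (m / n)^3 / m^3
  volume(out, extent / m, vol$origin)
}
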