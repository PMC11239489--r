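# Synthetic phantoms with the statistical structure the method assumes:
# Gaussian-blob "molecules" with a smooth mask, an optional disordered
# micelle-like region filled with low-frequency texture (dense but
# unstructured, excluded from the mask), half-map pairs sharing the phantom
# signal under independent colored noise, and projection datasets for the toy
# refinement loop. Blob phantoms are deliberate: they exercise the pipeline
# without implying atomic realism.

#' Phantom specification
#'
#' @param n grid edge (even). @param voxel_size Angstrom per voxel.
#' @param n_blobs number of Gaussian blobs.
#' @param blob_radius_range blob sigma range in Angstrom.
#' @param blob_weight_range peak density range.
#' @param disorder optional `list(center, radius)` (voxel units) of a
#'   micelle-like region filled with band-limited random texture and excluded
#'   from the mask; `NULL` for none.
#' @param disorder_resolution band limit of the disorder texture (Angstrom).
#' @param seed integer seed.
#' @export
phantom_spec <- function(n = 32L, voxel_size = 1.5, n_blobs = 10L,
                         blob_radius_range = c(1.2, 3), blob_weight_range = c(0.5, 1),
                         disorder = NULL, disorder_resolution = 20, seed = 1L) {
  structure(list(n = as.integer(n), voxel_size = voxel_size,
                 n_blobs = as.integer(n_blobs),
                 blob_radius_range = blob_radius_range,
                 blob_weight_range = blob_weight_range, disorder = disorder,
                 disorder_resolution = disorder_resolution,
                 seed = as.integer(seed)),
            class = "blush_phantom_spec")
}

#' Generate a blob phantom and its smooth molecule mask
#'
#' The phantom is a sum of anisotropic Gaussian blobs placed inside the
#' central two-thirds of the grid. The mask is a soft-edged indicator of the
#' blob region (1 at every blob center, smoothly decaying outside), from
#' which any disorder region is excluded; the disorder region itself is
#' filled with band-limited random texture.
#'
#' @param spec a [phantom_spec()].
#' @return `list(map, mask)`, both [volume()]s; mask values in `[0, 1]`.
#' @export
make_phantom <- function(spec) {
  n <- spec$n; vs <- spec$voxel_size
  with_seed(spec$seed, {
    g <- array(0, rep(n, 3))
    support <- array(0, rep(n, 3))
    ax <- (seq_len(n) - (n + 1) / 2) * vs
    if (spec$n_blobs > 0) {
      for (b in seq_len(spec$n_blobs)) {
        ctr <- runif(3, -n * vs / 3, n * vs / 3)
        # snap to the nearest voxel center so the mask is exactly 1 there
        ctr <- (round(ctr / vs - 0.5) + 0.5) * vs
        sig <- runif(3, spec$blob_radius_range[1], spec$blob_radius_range[2])
        wgt <- runif(1, spec$blob_weight_range[1], spec$blob_weight_range[2])
        rot <- random_rotation()
        d <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
        d <- sweep(d, 2, ctr) %*% rot
        q <- (d[, 1] / sig[1])^2 + (d[, 2] / sig[2])^2 + (d[, 3] / sig[3])^2
        g <- g + wgt * array(exp(-0.5 * q), rep(n, 3))
        # inflated-radius soft indicator for the mask
        qm <- q / 1.5^2
        support <- pmax(support, array(exp(-0.5 * qm), rep(n, 3)))
      }
    }
    mask <- support
    if (!is.null(spec$disorder)) {
      ctr <- (spec$disorder$center - (n + 1) / 2) * vs
      rd <- spec$disorder$radius * vs
      d <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
      d <- sweep(d, 2, ctr)
      ind <- array(exp(-0.5 * rowSums(d^2) / rd^2), rep(n, 3))
      tex <- lowpass_to_resolution(
        make_colored_noise(n, noise_spectrum(rep(1, n / 2 + 1)),
                           seed = spec$seed + 7L, voxel_size = vs),
        spec$disorder_resolution)
      g <- g + 0.8 * vol_grid(tex) * ind
      mask <- mask * (1 - pmin(ind / 0.5, 1))
      mask[mask < 0] <- 0
    }
    list(map = volume(g, vs), mask = volume(pmin(pmax(mask, 0), 1), vs))
  })
}

#' Noise model for synthetic data
#'
#' @param spectrum a [noise_spectrum()] or `"lorentzian"` / `"white"`.
#' @param amplitude RMS Fourier amplitude scale.
#' @param s0_frac knee shell as a fraction of the grid edge (lorentzian only).
#' @export
noise_model <- function(spectrum = "lorentzian", amplitude = 1, s0_frac = 1 / 8) {
  structure(list(spectrum = spectrum, amplitude = amplitude, s0_frac = s0_frac),
            class = "blush_noise_model")
}

noise_spectrum_for <- function(nm, n) {
  if (inherits(nm$spectrum, "blush_noise_spectrum")) return(nm$spectrum)
  switch(nm$spectrum,
         lorentzian = lorentzian_spectrum(n, s0 = nm$s0_frac * n, amplitude = nm$amplitude),
         white = noise_spectrum(rep(nm$amplitude, n / 2 + 1)),
         stop("unknown noise spectrum: ", nm$spectrum))
}

#' Simulate a half-map pair from a phantom
#'
#' Both halves share the phantom signal exactly; each receives an independent
#' colored-noise draw — the statistical contract noise2noise training relies
#' on.
#'
#' @param phantom signal [volume()]. @param mask mask [volume()] or `NULL`.
#' @param noise a [noise_model()]. @param seed integer seed.
#' @param id identifier.
#' @export
make_halfmap_pair <- function(phantom, mask = NULL, noise = noise_model(),
                              seed = NULL, id = "sim") {
  n <- vol_edge(phantom)
  sp <- noise_spectrum_for(noise, n)
  e0 <- make_colored_noise(n, sp, seed = derive_seed(seed, 0), voxel_size = phantom$voxel_size)
  e1 <- make_colored_noise(n, sp, seed = derive_seed(seed, 1), voxel_size = phantom$voxel_size)
  halfmap_pair(with_grid(phantom, vol_grid(phantom) + vol_grid(e0)),
               with_grid(phantom, vol_grid(phantom) + vol_grid(e1)),
               mask = mask, id = id)
}

#' Simulate a particle projection dataset
#'
#' Central-slice projections of the phantom at orientations cycled through the
#' given grid (recorded as ground truth), independent noise per particle, and
#' alternating half-set labels. The SNR annotation is the mean per-image
#' signal variance over the noise variance.
#'
#' @param phantom signal [volume()].
#' @param n_particles number of particles (>= 2).
#' @param grid_eulers orientation grid (`G x 3` ZYZ Euler angles).
#' @param noise_sd standard deviation of white pixel noise.
#' @param seed integer seed.
#' @export
make_particle_dataset <- function(phantom, n_particles, grid_eulers,
                                  noise_sd = 1, seed = NULL) {
  if (n_particles < 2) stop("need at least 2 particles")
  n <- vol_edge(phantom)
  FV <- project_fft(phantom)
  G <- nrow(grid_eulers)
  with_seed(seed, {
    idx <- ((seq_len(n_particles) - 1L) %% G) + 1L
    imgs <- array(0, c(n, n, n_particles))
    sigvar <- numeric(n_particles)
    for (p in seq_len(n_particles)) {
      rot <- euler_to_matrix(grid_eulers[idx[p], 1], grid_eulers[idx[p], 2],
                             grid_eulers[idx[p], 3])
      im <- project_volume(phantom, rot, FV = FV)
      sigvar[p] <- stats::var(as.vector(im))
      imgs[, , p] <- im + rnorm(n^2, sd = noise_sd)
    }
    particle_dataset(imgs,
                     eulers = grid_eulers[idx, , drop = FALSE],
                     half = (seq_len(n_particles) - 1L) %% 2L,
                     pixel_size = phantom$voxel_size,
                     snr = mean(sigvar) / noise_sd^2,
                     true_index = idx)
  })
}

#' Generate a training corpus of synthetic half-map pairs
#'
#' Varies the blob count and seed per pair; every pair carries its mask. If
#' `dir` is given, volumes are written as MRC files with a CSV manifest.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param template a [phantom_spec()] used as the base specification.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param dir optional output directory for MRC files + manifest.
#' @return List of [halfmap_pair()]s.
#' @export
make_training_corpus <- function(n_pairs, template = phantom_spec(),
                                 noise = noise_model(), seed = 1L, dir = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  pairs <- vector("list", n_pairs)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    sp <- template
    sp$seed <- derive_seed(seed, 10 * i)
    sp$n_blobs <- max(1L, template$n_blobs + ((i - 1L) %% 5L) - 2L)
    ph <- make_phantom(sp)
    pairs[[i]] <- make_halfmap_pair(ph$map, ph$mask, noise,
                                    seed = derive_seed(seed, 10 * i + 1),
                                    id = sprintf("sim%03d", i))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f0 <- file.path(dir, sprintf("sim%03d_half0.mrc", i))
      f1 <- file.path(dir, sprintf("sim%03d_half1.mrc", i))
      fm <- file.path(dir, sprintf("sim%03d_mask.mrc", i))
      write_mrc(pairs[[i]]$x0, f0); write_mrc(pairs[[i]]$x1, f1)
      write_mrc(ph$mask, fm)
      rows[[i]] <- data.frame(id = pairs[[i]]$id, half0 = f0, half1 = f1, mask = fm)
    }
  }
  if (!is.null(dir))
    utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  pairs
}
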