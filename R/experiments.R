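# Desk-scale study harnesses: fixed experimental conditions exercising the
# full pipeline (corpus -> augmentation -> training -> refinement) at sizes a
# single CPU handles in seconds to minutes. The conditions are package
# defaults chosen once (see the methods vignette) and shared between the test
# suite and the acceptance script.

#' Toy study conditions
#'
#' Reference configurations for the desk-scale experiments: a depth-2
#' denoiser on 16-voxel patches, a 16-pair corpus of 32-voxel phantoms at
#' 1.5 Angstrom voxels with colored half-map noise, and matching augmentation
#' ranges.
#'
#' @name toy_conditions
NULL

#' @rdname toy_conditions
#' @export
toy_denoiser_config <- function() {
  denoiser_config(depth = 2L, base_channels = 4L, dropout_rate = 0.5,
                  norm = "instance", patch_edge = 16L, voxel_size = 1.5)
}

#' @rdname toy_conditions
#' @export
toy_policy <- function() {
  augmentation_policy(res_range = c(4.5, 12), aniso_max = 1.5, trans_max = 1.5,
                      noise_amp_range = c(0.2, 1.0), noise_kind = "white",
                      r_max = 2L, patch_edge = 16L)
}

#' @param seed integer seed.
#' @param n_pairs corpus size.
#' @rdname toy_conditions
#' @export
toy_corpus <- function(seed, n_pairs = 16L) {
  make_training_corpus(n_pairs,
                       phantom_spec(n = 32L, voxel_size = 1.5, n_blobs = 10L),
                       noise_model("white", amplitude = 0.8), seed = seed)
}

#' Train the toy denoiser
#'
#' 200 Adam steps, mini-batches of 2 pairs (4 half-direction examples), on a
#' 16-pair synthetic corpus, under the [toy_conditions].
#'
#' @param seed integer seed for corpus, initialization and training.
#' @param steps training steps.
#' @param n_pairs corpus size.
#' @return `list(model, trace)` as from [train_denoiser()].
#' @export
train_toy_denoiser <- function(seed, steps = 200L, n_pairs = 16L) {
  corpus <- toy_corpus(seed, n_pairs)
  model <- build_model(toy_denoiser_config(), seed = seed)
  cfg <- training_config(steps = steps, batch_size = 2L, lr = 2e-3, seed = seed)
  train_denoiser(corpus, model, cfg, toy_policy())
}

#' Noise2noise recovery experiment
#'
#' Trains the toy denoiser on half-map pairs with independent noise, then
#' measures on held-out pairs whether the denoised map is closer (mean squared
#' error) to the clean phantom — which the network never saw — than the noisy
#' input is.
#'
#' @param seed integer seed.
#' @param steps,n_pairs training conditions.
#' @param n_eval held-out evaluation pairs.
#' @return `list(mse_noisy, mse_denoised, win, loss_first, loss_last)`.
#' @export
noise2noise_experiment <- function(seed, steps = 200L, n_pairs = 16L, n_eval = 2L) {
  fit <- train_toy_denoiser(seed, steps, n_pairs)
  mseN <- mseD <- numeric(n_eval)
  for (i in seq_len(n_eval)) {
    ph <- make_phantom(phantom_spec(n = 32L, voxel_size = 1.5, n_blobs = 10L,
                                    seed = derive_seed(seed, 500 + i)))
    pr <- make_halfmap_pair(ph$map, ph$mask, noise_model("white", amplitude = 0.8),
                            seed = derive_seed(seed, 600 + i))
    den <- denoise_volume(fit$model, pr$x0, patch_edge = 16L, overlap = 8L)
    mseN[i] <- mean((vol_grid(pr$x0) - vol_grid(ph$map))^2)
    mseD[i] <- mean((vol_grid(den) - vol_grid(ph$map))^2)
  }
  list(mse_noisy = mean(mseN), mse_denoised = mean(mseD),
       win = mean(mseD) < mean(mseN),
       loss_first = mean(head(fit$trace$loss, 20)),
       loss_last = mean(tail(fit$trace$loss, 20)))
}

#' Toy refinement dataset and configuration
#'
#' A 24-voxel phantom at 1.5 Angstrom voxels projected over a 192-orientation
#' grid (32 directions x 6 in-plane angles) with white pixel noise, plus the
#' low-pass filtered phantom as the initial reference.
#'
#' @param seed integer seed.
#' @param noise_sd pixel noise standard deviation.
#' @param n_particles particles (alternating half-sets).
#' @return `list(data, phantom, mask, grid, init)`.
#' @export
toy_refinement_dataset <- function(seed, noise_sd, n_particles = 320L) {
  ph <- make_phantom(phantom_spec(n = 24L, voxel_size = 1.5, n_blobs = 12L,
                                  seed = derive_seed(seed, 1)))
  grid <- make_orientation_grid(32L, 6L)
  data <- make_particle_dataset(ph$map, n_particles, grid, noise_sd = noise_sd,
                                seed = derive_seed(seed, 2))
  init <- apply_shell_filter(ph$map, make_lowpass(4L, 24L))
  list(data = data, phantom = ph$map, mask = ph$mask, grid = grid, init = init)
}

# integrated FSC of a map against the known phantom (sum over shells 1..n/2)
integrated_fsc <- function(map, phantom) {
  sum(compute_fsc(map, phantom)$values[-1])
}

#' Low-SNR benefit experiment
#'
#' At a noise level where baseline refinement misassigns a large fraction of
#' orientations, compares baseline and denoiser-regularized refinement by the
#' shell-integrated FSC of the final map against the known phantom.
#'
#' @param model a trained `blush_denoiser`.
#' @param seed integer seed.
#' @param noise_sd pixel noise standard deviation (study condition).
#' @param iterations refinement iterations.
#' @param n_particles dataset size (the larger default keeps the half-map FSC
#'   cutoff rho high enough that the rho - 2 trailing band still carries
#'   alignment information at this grid size).
#' @return `list(misassign_baseline, int_fsc_baseline, int_fsc_blush, win)`.
#' @export
low_snr_experiment <- function(model, seed, noise_sd = 5, iterations = 3L,
                               n_particles = 480L) {
  d <- toy_refinement_dataset(seed, noise_sd, n_particles)
  base_cfg <- refinement_config(iterations, d$grid, mode = "baseline",
                                initial_reference = d$init, mask = d$mask,
                                rand_shell = 8L, seed = seed)
  blush_cfg <- refinement_config(iterations, d$grid, mode = "blush",
                                 initial_reference = d$init, mask = d$mask,
                                 rand_shell = 8L, seed = seed)
  rb <- refine(d$data, NULL, base_cfg)
  rx <- refine(d$data, model, blush_cfg)
  mis <- mean(rb$assignments$index != d$data$true_index)
  list(misassign_baseline = mis,
       int_fsc_baseline = integrated_fsc(rb$map, d$phantom),
       int_fsc_blush = integrated_fsc(rx$map, d$phantom),
       win = integrated_fsc(rx$map, d$phantom) >= integrated_fsc(rb$map, d$phantom))
}

# Hermitian-preserving phase randomization of a 2D image beyond a shell
randomize_phases_image <- function(img, shell_start, seed = NULL) {
  n <- dim(img)[1]
  FV <- fft(img)
  W <- fft(with_seed(seed, matrix(rnorm(n^2), n, n)))
  mw <- Mod(W)
  ph <- ifelse(mw > 1e-300, W / mw, 1 + 0i)
  f <- freq_index(n)
  s <- round(sqrt(outer(f^2, f^2, "+")))
  sel <- s >= shell_start
  FV[sel] <- Mod(FV[sel]) * ph[sel]
  Re(fft(FV, inverse = TRUE)) / n^2
}

#' Phase-randomization overfitting guard experiment
#'
#' Replaces all image phases beyond shell `s0` with random phases (destroying
#' any signal there), refines, and reports the mean solvent-corrected
#' half-map FSC beyond `s0` of the final half-maps: any appreciable positive
#' mean is overfitting manufactured by the reconstruction process.
#'
#' @param model a trained `blush_denoiser` (or `NULL` for baseline mode).
#' @param seed integer seed.
#' @param mode `"blush"` or `"baseline"`.
#' @param s0 randomization shell.
#' @param noise_sd pixel noise standard deviation.
#' @param iterations refinement iterations.
#' @param spectral_trailing passed to [refinement_config()].
#' @return `list(mean_fsc_beyond, fsc)`.
#' @export
phase_randomization_experiment <- function(model, seed, mode = "blush", s0 = 6L,
                                           noise_sd = 1, iterations = 3L,
                                           spectral_trailing = TRUE) {
  d <- toy_refinement_dataset(seed, noise_sd)
  imgs <- d$data$images
  for (p in seq_len(dim(imgs)[3]))
    imgs[, , p] <- randomize_phases_image(imgs[, , p], s0,
                                          seed = derive_seed(seed, 900 + p))
  d$data$images <- imgs
  cfg <- refinement_config(iterations, d$grid, mode = mode,
                           initial_reference = d$init, mask = d$mask,
                           rand_shell = s0, spectral_trailing = spectral_trailing,
                           seed = seed)
  res <- refine(d$data, model, cfg)
  # margin 0: correct from s0 itself, so mask-spillover correlation in the
  # first shells above the randomization cutoff is removed rather than
  # reported as spurious signal (only a handful of shells exist at this scale)
  fsc <- solvent_corrected_fsc(res$half0, res$half1, d$mask, rand_shell = s0,
                               n_rand = 2L, margin = 0L,
                               seed = derive_seed(seed, 999))
  n <- vol_edge(res$half0)
  beyond <- fsc$values[(s0 + 2):(n / 2 + 1)]
  list(mean_fsc_beyond = mean(beyond), fsc = fsc)
}
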