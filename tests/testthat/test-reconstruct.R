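test_that("Euler angles give proper rotations; projection at identity is the z-sum", {
  R <- euler_to_matrix(0.4, 1.1, 2.0)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(euler_to_matrix(0, 0, 0), diag(3))
  # a volume band-limited inside the Nyquist ball projects exactly
  v <- fix_vol16()
  expect_lt(max(abs(project_volume(v, diag(3)) - apply(v$grid, c(1, 2), sum))), 1e-9)
})

test_that("dense noiseless backprojection recovers the phantom", {
  ph <- make_phantom(phantom_spec(n = 16L, voxel_size = 1.5, n_blobs = 8L, seed = 5))
  grid <- make_orientation_grid(300L, 4L)
  ds <- make_particle_dataset(ph$map, 1200L, grid, noise_sd = 1e-8, seed = 6)
  h <- backproject_halfset(ds, 0L)
  fsc <- compute_fsc(h, ph$map)$values
  expect_true(all(fsc[2:7] > 0.95))   # shells 1..6 = 80% of Nyquist (8)
})

test_that("backprojection is linear and maps zero images to the zero volume", {
  ph <- fix_phantom24()
  grid <- make_orientation_grid(16L, 2L)
  ds <- make_particle_dataset(ph$map, 24L, grid, noise_sd = 0.5, seed = 7)
  h1 <- backproject_halfset(ds, 0L)
  ds2 <- ds; ds2$images <- 2 * ds$images
  expect_equal(backproject_halfset(ds2, 0L)$grid, 2 * h1$grid, tolerance = 1e-9)
  ds0 <- ds; ds0$images[] <- 0
  expect_true(all(backproject_halfset(ds0, 0L)$grid == 0))
  expect_error(backproject_halfset(ds, 2L), "0/1|empty")
})

test_that("projection matching recovers true orientations on noiseless data", {
  ph <- fix_phantom24()
  grid <- make_orientation_grid(8L, 4L)
  ds <- make_particle_dataset(ph$map, 40L, grid, noise_sd = 1e-8, seed = 8)
  al <- align_particles(ds, ph$map, ph$map, grid)
  expect_equal(al$index, ds$true_index)
  # zero references: all correlations tie, lowest grid index wins
  z <- volume(array(0, rep(24, 3)), 1.5)
  expect_true(all(align_particles(ds, z, z, grid)$index == 1L))
  # corrupting one particle leaves the others' assignments unchanged
  ds2 <- ds; ds2$images[, , 5] <- ds2$images[, , 5] + matrix(rnorm(24^2, sd = 50), 24)
  al2 <- align_particles(ds2, ph$map, ph$map, grid)
  expect_equal(al2$index[-5], al$index[-5])
})

test_that("the trailing filter splices denoised, zero and fallback bands as specified", {
  set.seed(40)
  den <- volume(array(rnorm(24^3), rep(24, 3)), 1.5)
  fb <- volume(array(rnorm(24^3), rep(24, 3)), 1.5)
  sidx <- blushr:::shell_index(24L)
  # rho within the denoiser band (3 A on a 1.5 A grid = Nyquist here):
  # trail = rho - 2 passes denoised, everything above is zeroed
  ts <- trailing_state(10L, 24L, 1.5, denoiser_nyquist_A = 3)
  expect_equal(ts$trail_shell, 8L); expect_equal(ts$nyquist_shell, 12L)
  out <- trailing_filter(den, fb, ts)
  FO <- fft(out$grid); FD <- fft(den$grid)
  expect_lt(max(Mod(FO[sidx >= 10L])), 1e-8)               # shells >= 9 are zero
  keep <- sidx <= 9L
  expect_lt(max(Mod(FO[keep] - FD[keep])), 1e-6)           # denoised passes bit-like
  # rho beyond the denoiser Nyquist: fallback populates the shells above it
  ts2 <- trailing_state(10L, 24L, 1.5, denoiser_nyquist_A = 6)  # nyquist shell 6
  out2 <- trailing_filter(den, fb, ts2)
  FO2 <- fft(out2$grid); FB <- fft(fb$grid)
  hi <- sidx > 7L
  expect_lt(max(Mod(FO2[hi] - FB[hi])), 1e-6)
  lo <- sidx <= 7L
  expect_lt(max(Mod(FO2[lo] - FD[lo])), 1e-6)
  # trail below the Nyquist shell with rho beyond it: a zeroed gap in between
  ts3 <- trailing_state(9L, 24L, 1.5, denoiser_nyquist_A = 4.5)  # trail 7, nyq 8
  out3 <- trailing_filter(den, fb, ts3)
  FO3 <- fft(out3$grid)
  expect_lt(max(Mod(FO3[sidx == 9L])), 1e-8)               # shell 8 zeroed gap
  expect_lt(max(Mod(FO3[sidx > 9L] - FB[sidx > 9L])), 1e-6)
  expect_lt(max(Mod(FO3[sidx <= 8L] - FD[sidx <= 8L])), 1e-6)
})

test_that("the final Wiener filter applies the 2f/(1+f) gain per shell", {
  set.seed(41)
  h0 <- volume(array(rnorm(16^3), rep(16, 3)), 1.5)
  h1 <- volume(h0$grid + 0.1 * rnorm(16^3), 1.5)
  ones <- blushr:::fsc_curve(rep(1, 9), 16L, 1.5)
  out <- wiener_filter_final(h0, h1, ones)
  expect_equal(out$grid, (h0$grid + h1$grid) / 2, tolerance = 1e-9)
  zv <- blushr:::fsc_curve(rep(0, 9), 16L, 1.5)
  expect_lt(max(abs(wiener_filter_final(h0, h1, zv)$grid)), 1e-10)
  third <- blushr:::fsc_curve(rep(1 / 3, 9), 16L, 1.5)
  outt <- wiener_filter_final(h0, h1, third)
  expect_equal(outt$grid, (h0$grid + h1$grid) / 2 * 0.5, tolerance = 1e-9)
  expect_equal(blushr:::wiener_gain(blushr:::fsc_curve(c(1, 1/3, 0, -0.5), 8L, 1))[4], 0)
})

test_that("baseline refinement converges on high-SNR data", {
  ph <- fix_phantom24()
  grid <- make_orientation_grid(60L, 6L)      # dense enough that gridding error
  ds <- make_particle_dataset(ph$map, 720L, grid, noise_sd = 0.2, seed = 44)
  init <- apply_shell_filter(ph$map, make_lowpass(4L, 24L))
  cfg <- refinement_config(2L, grid, mode = "baseline", initial_reference = init,
                           mask = ph$mask, rand_shell = 8L, seed = 44)
  r <- refine(ds, NULL, cfg)
  fsc <- compute_fsc(r$map, ph$map)$values
  expect_true(all(fsc[2:7] > 0.9))   # up to half-Nyquist
  expect_equal(nrow(r$trace), 2L)
  expect_true(all(r$trace$trail_shell < r$trace$rho))  # resolution safety
})

test_that("blush with the identity denoiser reduces to baseline", {
  ph <- fix_phantom24()
  grid <- make_orientation_grid(12L, 4L)
  ds <- make_particle_dataset(ph$map, 96L, grid, noise_sd = 1, seed = 45)
  init <- apply_shell_filter(ph$map, make_lowpass(4L, 24L))
  idm <- build_model(denoiser_config(depth = 2L, base_channels = 4L,
                                     patch_edge = 16L), seed = 1)
  common <- list(iterations = 2L, grid_eulers = grid, initial_reference = init,
                 mask = ph$mask, rand_shell = 8L, keep_refs = TRUE, seed = 45)
  rb <- refine(ds, NULL, do.call(refinement_config, c(common, mode = "baseline")))
  rx <- refine(ds, idm, do.call(refinement_config, c(common, mode = "blush")))
  # references agree below the trailing cutoff
  trail <- rx$trace$trail_shell[1]
  sidx <- blushr:::shell_index(24L)
  low <- sidx <= trail + 1L
  FB <- fft(rb$refs[[1]]$ref0$grid); FX <- fft(rx$refs[[1]]$ref0$grid)
  expect_lt(max(Mod(FB[low] - FX[low])) / max(Mod(FB[low])), 1e-5)
  # without spectral trailing the whole reference band coincides, so the two
  # modes make identical orientation assignments at every iteration
  rx2 <- refine(ds, idm, do.call(refinement_config,
                                 c(common, mode = "blush", spectral_trailing = FALSE)))
  expect_identical(rx2$assignment_history, rb$assignment_history)
  expect_identical(rx2$assignments$index, rb$assignments$index)
})

test_that("the classification hook denoises without trailing and preserves shape", {
  idm <- build_model(denoiser_config(depth = 2L, base_channels = 4L,
                                     patch_edge = 16L), seed = 2)
  v <- fix_vol32()
  out <- classify_denoise_hook(v, idm)
  expect_equal(dim(out$grid), dim(v$grid))
  expect_equal(out$voxel_size, v$voxel_size)
  expect_lt(max(abs(out$grid - v$grid)), 1e-5)
  bad <- v; bad$grid[1] <- Inf
  expect_error(classify_denoise_hook(bad, idm), "finite")
})

test_that("STAR particle metadata round-trips", {
  ph <- fix_phantom24()
  grid <- make_orientation_grid(6L, 2L)
  ds <- make_particle_dataset(ph$map, 10L, grid, noise_sd = 1, seed = 50)
  f <- withr::local_tempfile(fileext = ".star")
  write_star_particles(ds, f)
  ds2 <- read_star_particles(f, images = ds$images, pixel_size = ds$pixel_size)
  expect_equal(ds2$eulers, ds$eulers, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ds2$half, ds$half)
})
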