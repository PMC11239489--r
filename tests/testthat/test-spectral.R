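test_that("FSC of a volume with itself is 1 and with its negation -1", {
  v <- fix_vol32()
  self <- compute_fsc(v, v)
  expect_length(self$values, 17L)
  expect_equal(self$values, rep(1, 17), tolerance = 1e-12)
  neg <- compute_fsc(v, volume(-v$grid, v$voxel_size))
  expect_equal(neg$values, rep(-1, 17), tolerance = 1e-12)
  expect_error(compute_fsc(v, fix_vol16()), "identical dimensions")
})

test_that("FSC is symmetric and scale-invariant", {
  set.seed(5)
  a <- volume(array(rnorm(16^3), rep(16, 3)), 1.5)
  b <- volume(array(rnorm(16^3), rep(16, 3)), 1.5)
  expect_identical(compute_fsc(a, b)$values, compute_fsc(b, a)$values)
  b3 <- volume(3.7 * b$grid, 1.5)
  expect_equal(compute_fsc(a, b3)$values, compute_fsc(a, b)$values, tolerance = 1e-12)
})

test_that("FSC of independent white noise stays within its null bounds", {
  n <- 32L
  cnt <- blushr:::shell_counts(n)
  frac_ok <- replicate(40, {
    a <- volume(array(rnorm(n^3), rep(n, 3)), 1)
    b <- volume(array(rnorm(n^3), rep(n, 3)), 1)
    f <- compute_fsc(a, b)$values[-1]
    mean(abs(f) <= 3 / sqrt(cnt[-1]))
  })
  expect_gte(mean(frac_ok), 0.95)
})

test_that("phase randomization preserves amplitudes and power exactly", {
  v <- fix_vol32()
  pr <- randomize_phases(v, 5L, seed = 11)
  p_in <- power_spectrum(v); p_out <- power_spectrum(pr)
  expect_equal(p_out, p_in, tolerance = 1e-6)
  expect_equal(sum(pr$grid^2), sum(v$grid^2), tolerance = 1e-9)  # Parseval
  # components below the randomized band are untouched
  FA <- fft(v$grid); FB <- fft(pr$grid)
  low <- blushr:::shell_index(32L) < 5L + 1L
  expect_lt(max(Mod(FA[low] - FB[low])), 1e-8 * max(Mod(FA)))
  # determinism under seed
  expect_identical(pr$grid, randomize_phases(v, 5L, seed = 11)$grid)
})

test_that("FSC against a phase-randomized copy splits at the randomization shell", {
  v <- fix_vol32()
  lows <- highs <- NULL
  for (s in 1:50) {
    f <- compute_fsc(v, randomize_phases(v, 8L, seed = s))$values
    lows <- c(lows, f[2:8])        # shells 1..7
    highs <- c(highs, f[10:17])    # shells 9..16
  }
  expect_true(all(lows > 0.999))
  expect_lt(abs(mean(highs)), 0.05)
})

test_that("solvent correction leaves a signal-free masked pair near zero", {
  set.seed(77)
  means <- replicate(8, {
    a <- volume(array(rnorm(24^3), rep(24, 3)), 1.5)
    b <- volume(array(rnorm(24^3), rep(24, 3)), 1.5)
    f <- solvent_corrected_fsc(a, b, mask = NULL, rand_shell = 6L, seed = sample.int(1e6, 1))
    mean(f$values[9:13])
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("solvent correction applies the (t - n)/(1 - n) formula beyond the margin", {
  # a pair whose masked FSC is strongly inflated by a tight mask
  ph <- fix_phantom24()
  pr <- make_halfmap_pair(ph$map, NULL, noise_model("white", amplitude = 1.2), seed = 3)
  raw <- compute_fsc(pr$x0, pr$x1)$values
  m <- ph$mask
  masked <- compute_fsc(volume(pr$x0$grid * m$grid, 1.5),
                        volume(pr$x1$grid * m$grid, 1.5))$values
  corr <- solvent_corrected_fsc(pr$x0, pr$x1, m, rand_shell = 5L,
                                n_rand = 3L, seed = 9)$values
  # below rand_shell + margin the corrected curve IS the masked curve
  expect_equal(corr[1:8], masked[1:8], tolerance = 1e-12)
  # beyond it the mask-induced inflation is removed: corrected tracks the
  # unmasked curve far better than the masked one does
  idx <- 9:13
  expect_lt(mean(abs(corr[idx] - raw[idx])), mean(abs(masked[idx] - raw[idx])))
})

test_that("estimate_rho implements the first-crossing rule", {
  mk <- function(vals) blushr:::fsc_curve(vals, n = 2L * (length(vals) - 1L), voxel_size = 1)
  expect_equal(estimate_rho(mk(c(1, 1, 0.9, 0.5, 0.10, 0.3, 0.2, 0.1, 0, 0, 0))), 3L)
  expect_equal(estimate_rho(mk(rep(0.5, 9))), 8L)         # never below -> n/2
  expect_equal(estimate_rho(mk(c(1, 0.1, 0.9, 0.9, 0.9))), 1L)  # below at shell 1
  v <- fix_vol16()
  expect_equal(estimate_rho(compute_fsc(v, v)), 8L)        # self-FSC -> n/2
})

test_that("low-pass shell filters preserve DC and kill power beyond a hard cutoff", {
  n <- 16L
  cv <- volume(array(4.2, rep(n, 3)), 1.5)
  out <- apply_shell_filter(cv, make_lowpass(3L, n))
  expect_lt(max(abs(out$grid - 4.2)), 1e-9)
  set.seed(2)
  w <- volume(array(rnorm(n^3), rep(n, 3)), 1.5)
  hp <- apply_shell_filter(w, make_lowpass(5L, n))
  expect_lt(max(power_spectrum(hp)[7:9]), 1e-20)
  expect_equal(resolution_to_shell(15, 64L, 1.5), 6L)      # 64*1.5/15 = 6.4 -> 6
  g <- make_lowpass(6L, n, edge_width = 3L)$gain
  expect_true(all(g >= 0 & g <= 1) && g[1] == 1 && g[8] == 0)
})

test_that("anisotropic Gaussian filter matches the real-space kernel", {
  # C = 0 is the identity
  v <- fix_vol16()
  expect_lt(max(abs(anisotropic_gaussian_filter(v, matrix(0, 3, 3))$grid - v$grid)), 1e-10)
  # isotropic filter of a point source equals the (circularly wrapped) sampled
  # Gaussian kernel of standard deviation sigma
  sig <- 2.0
  d <- array(0, rep(16, 3)); d[9, 9, 9] <- 1
  fd <- anisotropic_gaussian_filter(volume(d, 1.0), diag(3) * sig^2)
  ax <- (1:16) - 9
  k1 <- vapply(ax, function(x) sum(exp(-(x + 16 * (-2:2))^2 / (2 * sig^2))), 1)
  K <- outer(outer(k1, k1), k1); K <- K / sum(K)
  expect_lt(sqrt(mean((fd$grid - K)^2)) / sqrt(mean(K^2)), 1e-4)
  # a very large variance along z wipes out variation along z lines
  fz <- anisotropic_gaussian_filter(v, diag(c(0, 0, 1e6)))
  zvar <- mean(apply(fz$grid, c(1, 2), stats::var))
  expect_lt(zvar, 1e-6 * mean(apply(v$grid, c(1, 2), stats::var)))
  expect_error(anisotropic_gaussian_filter(v, matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)), "symmetric")
})

test_that("the Gaussian filter commutes with axis permutations of C", {
  v <- fix_vol16()
  C <- gaussian_covariance(6, aniso = c(1, 1.4, 2), rotation = diag(3))
  perm <- c(3, 1, 2)
  P <- diag(3)[perm, ]
  f1 <- aperm(anisotropic_gaussian_filter(v, C)$grid, perm)
  f2 <- anisotropic_gaussian_filter(volume(aperm(v$grid, perm), v$voxel_size),
                                    P %*% C %*% t(P))$grid
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("gaussian_covariance gives gain 0.5 at the cutoff frequency", {
  R <- 8
  C <- gaussian_covariance(R)
  k <- 1 / R
  expect_equal(exp(-2 * pi^2 * k^2 * C[1, 1]), 0.5, tolerance = 1e-12)
  expect_identical(gaussian_covariance(Inf), matrix(0, 3, 3))
})

test_that("colored noise is seed-deterministic with the requested spectrum", {
  n <- 16L
  expect_true(all(make_colored_noise(n, noise_spectrum(rep(0, 9)), seed = 1)$grid == 0))
  a <- make_colored_noise(n, lorentzian_spectrum(n), seed = 42)
  b <- make_colored_noise(n, lorentzian_spectrum(n), seed = 42)
  expect_identical(a$grid, b$grid)
  # flat spectrum: empirical per-shell power flat within 3 standard errors
  draws <- 400L
  acc <- matrix(0, draws, n / 2 + 1)
  for (i in seq_len(draws))
    acc[i, ] <- power_spectrum(make_colored_noise(n, noise_spectrum(rep(1, 9)), seed = 1000 + i))
  mu <- colMeans(acc); se <- apply(acc, 2, stats::sd) / sqrt(draws)
  expect_true(all(abs(mu - 1) <= 3 * se + 1e-8))
})
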