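test_that("apply_H with no filter, no transform and full crop is the identity on standardized input", {
  v <- fix_vol16()
  g <- standardize_patch(v$grid)
  out <- apply_H(volume(g, 1.5), matrix(0, 3, 3), affine_transform(),
                 c(1, 1, 1), patch_edge = 16L)
  expect_lt(max(abs(out - g)), 1e-10)
})

test_that("every augmented patch satisfies the standardization contract", {
  pair <- toy_corpus(3, 2)[[1]]
  pol <- toy_policy()
  for (s in 1:8) {
    ex <- build_example(pair, s %% 2, seed = s, policy = pol)
    for (p in list(ex$y, ex$ybar)) {
      expect_lt(abs(mean(p)), 1e-6)
      expect_lt(abs(sqrt(mean((p - mean(p))^2)) - 1), 1e-6)
      expect_equal(dim(p), rep(16L, 3))
    }
    expect_true(ex$r %in% 0:2)
  }
})

test_that("a 90-degree rotation in H matches exact array rotation", {
  v <- fix_vol16()
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)   # +90 deg about z
  out <- apply_H(v, matrix(0, 3, 3), affine_transform(Rz), c(5, 5, 5), 8L)
  # voxel-center algebra: rotated(x,y,z) = orig(y, n+1-x, z)
  n <- 16L
  rot <- array(0, rep(n, 3))
  for (x in 1:n) for (y in 1:n) rot[x, y, ] <- v$grid[y, n + 1 - x, ]
  expected <- standardize_patch(rot[5:12, 5:12, 5:12])
  expect_lt(max(abs(out - expected)), 1e-4)
})

test_that("the input patch is built from the OTHER half (cross-half indexing)", {
  set.seed(9)
  x0 <- volume(array(rnorm(32^3), rep(32, 3)), 1.5)
  x1 <- volume(array(rnorm(32^3), rep(32, 3)), 1.5)
  pair <- halfmap_pair(x0, x1)
  spec <- sample_spec(4, toy_policy(), 32L, 1.5)
  spec$noise <- noise_spectrum(rep(0, 17))   # no noise
  spec$C <- matrix(0, 3, 3)
  spec$A <- affine_transform()
  y0 <- make_input_y(pair, 0, spec)
  cc <- spec$crop_corner; e <- spec$patch_edge
  crop1 <- standardize_patch(x1$grid[cc[1]:(cc[1] + e - 1), cc[2]:(cc[2] + e - 1),
                                     cc[3]:(cc[3] + e - 1)])
  expect_lt(max(abs(y0 - crop1)), 1e-10)     # k=0 input comes from x1
  # identical halves + no noise: the two passes coincide
  pair2 <- halfmap_pair(x0, x0)
  expect_equal(make_input_y(pair2, 0, spec), make_input_y(pair2, 1, spec))
  # determinism under the stored noise seeds
  spec2 <- sample_spec(4, toy_policy(), 32L, 1.5)
  expect_identical(make_input_y(pair, 0, spec2), make_input_y(pair, 0, spec2))
})

test_that("target construction blends the map with its low-pass fill by the mask", {
  set.seed(10)
  n <- 32L
  x <- volume(array(rnorm(n^3), rep(n, 3)), 1.5)
  mask_bin <- array(0, rep(n, 3)); mask_bin[1:16, , ] <- 1
  pair <- halfmap_pair(x, x, mask = volume(mask_bin, 1.5))
  spec <- sample_spec(5, toy_policy(), n, 1.5)
  spec$C_bar <- matrix(0, 3, 3); spec$A <- affine_transform()
  spec$crop_corner <- c(1L, 1L, 1L); spec$patch_edge <- 32L
  yb <- make_target_ybar(pair, 0, spec)
  lp <- lowpass_to_resolution(x, spec$lowpass_fill_resolution)
  blend <- x$grid * mask_bin + lp$grid * (1 - mask_bin)
  expect_lt(max(abs(yb - standardize_patch(blend))), 1e-10)
  # all-ones mask (or absent mask) reduces to H applied to the map itself
  ones <- halfmap_pair(x, x, mask = volume(array(1, rep(n, 3)), 1.5))
  none <- halfmap_pair(x, x)
  expect_equal(make_target_ybar(ones, 0, spec), standardize_patch(x$grid))
  expect_equal(make_target_ybar(none, 0, spec), standardize_patch(x$grid))
  # all-zeros mask reduces to H applied to the low-pass fill
  zeros <- halfmap_pair(x, x, mask = volume(array(0, rep(n, 3)), 1.5))
  expect_lt(max(abs(make_target_ybar(zeros, 0, spec) - standardize_patch(lp$grid))), 1e-10)
})

test_that("sample_spec is deterministic and honors its constraints", {
  pol <- toy_policy()
  s1 <- sample_spec(123, pol, 32L, 1.5)
  s2 <- sample_spec(123, pol, 32L, 1.5)
  expect_identical(s1$crop_corner, s2$crop_corner)
  expect_identical(s1$A$rotation, s2$A$rotation)
  expect_identical(s1$r, s2$r)
  # the input-side filter never passes more resolution than the target side
  for (s in 1:300) {
    sp <- sample_spec(s, pol, 32L, 1.5)
    expect_gte(sp$res_in, sp$res_bar)
    expect_gte(min(eigen(sp$C, symmetric = TRUE)$values), -1e-9)
    expect_true(abs(det(sp$A$rotation) - 1) < 1e-6)
  }
})

test_that("recycle counts are drawn uniformly", {
  pol <- augmentation_policy(patch_edge = 16L, r_max = 5L)
  rs <- vapply(1:3000, function(s) sample_spec(s, pol, 32L, 1.5)$r, 1L)
  freq <- tabulate(rs + 1L, 6L) / 3000
  se <- sqrt((1 / 6) * (5 / 6) / 3000)
  expect_true(all(abs(freq - 1 / 6) <= 4 * se))
})

test_that("a degenerate pair with matched filters gives y equal to ybar", {
  set.seed(12)
  x <- volume(array(rnorm(32^3), rep(32, 3)), 1.5)
  pair <- halfmap_pair(x, x)
  spec <- sample_spec(6, toy_policy(), 32L, 1.5)
  spec$noise <- noise_spectrum(rep(0, 17))
  spec$C_bar <- spec$C
  y <- make_input_y(pair, 0, spec)
  yb <- make_target_ybar(pair, 0, spec)
  expect_lt(max(abs(y - yb)), 1e-10)
})

test_that("augmentation noise streams for the two halves are independent", {
  spec <- sample_spec(31, toy_policy(), 32L, 1.5)
  e0 <- make_colored_noise(32L, spec$noise, seed = spec$noise_seeds[1])
  e1 <- make_colored_noise(32L, spec$noise, seed = spec$noise_seeds[2])
  expect_lt(abs(cor(as.vector(e0$grid), as.vector(e1$grid))), 0.05)
})
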