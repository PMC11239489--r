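test_that("volume constructor enforces its invariants", {
  expect_error(volume(array(0, c(16, 16, 18)), 1.5), "cubic")
  expect_error(volume(array(0, rep(17, 3)), 1.5), "even")
  expect_error(volume(array(0, rep(8, 3)), 1.5), ">= 16")
  expect_error(volume(array(0, rep(16, 3)), -1), "positive")
  g <- array(0, rep(16, 3)); g[1] <- NaN
  expect_error(volume(g, 1), "finite")
  v <- volume(array(1, rep(16, 3)), 1.5, origin = c(3, 0, 0))
  expect_s3_class(v, "blush_volume")
  expect_equal(v$origin[1], 3)
})

test_that("MRC round trip preserves grid, voxel size and origin", {
  v <- fix_vol32()
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(v, f)
  r1 <- read_mrc(f)
  expect_equal(r1$voxel_size, 1.5, tolerance = 1e-6)
  expect_equal(dim(r1$grid), dim(v$grid))
  # first pass is float32 quantization; a second pass must be bit-faithful
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(r1, f2)
  r2 <- read_mrc(f2)
  expect_identical(r2$grid, r1$grid)
  expect_lt(max(abs(r1$grid - v$grid)), 1e-6)
})

test_that("MRC header encodes cell length = n * voxel_size", {
  v <- volume(array(0, rep(32, 3)), 1.5)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(v, f)
  con <- file(f, "rb")
  hdr <- readBin(con, "raw", 1024)
  close(con)
  cella <- readBin(hdr[41:52], "numeric", n = 3, size = 4, endian = "little")
  expect_equal(cella, rep(48, 3), tolerance = 1e-5)
})

test_that("malformed and truncated MRC files are rejected, not half-read", {
  v <- volume(array(rnorm(16^3), rep(16, 3)), 1.5)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(v, f)
  full <- readBin(f, "raw", file.size(f))
  ft <- withr::local_tempfile(fileext = ".mrc")
  writeBin(full[1:(1024 + 100)], ft)
  expect_error(read_mrc(ft), "truncated")
  # corrupt MODE field (word 4)
  bad <- full
  bad[13:16] <- writeBin(7L, raw(), size = 4, endian = "little")
  fb <- withr::local_tempfile(fileext = ".mrc")
  writeBin(bad, fb)
  expect_error(read_mrc(fb), "MODE")
  expect_error(read_mrc(withr::local_tempfile()), "exist")
})

test_that("writing non-finite data is refused before any bytes hit disk", {
  v <- fix_vol16()
  v$grid[1] <- NA
  f <- withr::local_tempfile(fileext = ".mrc")
  expect_error(write_mrc(v, f), "non-finite")
  expect_false(file.exists(f))
})

test_that("non-cubic maps are rejected unless padding is requested", {
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrcs_stack(array(rnorm(16 * 16 * 10), c(16, 16, 10)), 1.2, f)
  expect_error(read_mrc(f), "even cube")
  v <- read_mrc(f, pad_to_cube = TRUE)
  n <- dim(v$grid)[1]
  expect_true(n %% 2 == 0 && n >= 16)
  expect_equal(dim(v$grid), rep(n, 3L))
})

test_that("rescale_voxel_size follows the Fourier-crop contract", {
  v <- fix_vol32()
  expect_identical(rescale_voxel_size(v, 1.5), v)        # identity at same spacing
  v10 <- volume(v$grid, 1.0)
  r <- rescale_voxel_size(v10, 1.5)
  expect_equal(dim(r$grid)[1], 22L)                      # round(32/1.5)=21 -> even 22
  expect_equal(r$voxel_size, 32 / 22, tolerance = 1e-12) # extent 32 A preserved
  expect_equal(mean(r$grid), mean(v10$grid), tolerance = 1e-6)  # DC preserved
  expect_error(rescale_voxel_size(v10, 3), "< 16")
})

test_that("rescaling down then up preserves a smooth phantom", {
  ph <- make_phantom(phantom_spec(n = 32L, voxel_size = 1.0, n_blobs = 8L,
                                  blob_radius_range = c(2, 4), seed = 7))
  up <- rescale_voxel_size(rescale_voxel_size(ph$map, 1.45), 1.0)
  expect_equal(dim(up$grid), dim(ph$map$grid))
  ctr <- 5:28   # soft central region, excluding the edge
  expect_gt(cor(as.vector(up$grid[ctr, ctr, ctr]),
                as.vector(ph$map$grid[ctr, ctr, ctr])), 0.99)
})

test_that("tiling covers the volume and blending is a partition of unity", {
  cases <- list(c(16, 16, 0), c(32, 16, 8), c(32, 16, 4), c(48, 32, 16),
                c(24, 16, 8), c(20, 16, 2))
  for (cs in cases) {
    n <- cs[1]; e <- cs[2]; ov <- cs[3]
    g <- tile_volume(array(0, rep(n, 3)), e, ov)
    ones <- lapply(seq_len(nrow(g$origins)), function(i) array(1, rep(e, 3)))
    w <- stitch_patches(ones, g)
    expect_lt(max(abs(w - 1)), 1e-6)   # weights sum to 1 at every voxel
  }
  g1 <- tile_volume(array(0, rep(16, 3)), 16, 0)
  expect_equal(nrow(g1$origins), 1L)
  g8 <- tile_volume(array(0, rep(96, 3)), 64, 32)
  expect_equal(nrow(g8$origins), 8L)
  expect_equal(sort(unique(g8$origins[, 1])), c(1L, 33L))
})

test_that("tile then stitch is the identity; degenerate patch sets behave", {
  v <- fix_vol32()
  for (cs in list(c(16, 8), c(16, 4), c(32, 0))) {
    g <- tile_volume(v, cs[1], cs[2])
    st <- stitch_patches(extract_patches(v, g), g, template = v)
    expect_lt(max(abs(st$grid - v$grid)), 1e-6)
  }
  g <- tile_volume(v, 16, 8)
  k <- nrow(g$origins)
  zeros <- stitch_patches(replicate(k, array(0, rep(16, 3)), simplify = FALSE), g)
  expect_true(all(zeros == 0))
  consts <- stitch_patches(replicate(k, array(3.5, rep(16, 3)), simplify = FALSE), g)
  expect_lt(max(abs(consts - 3.5)), 1e-6)
  expect_error(stitch_patches(list(array(0, rep(16, 3))), g), "does not match")
})
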