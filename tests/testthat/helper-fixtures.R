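# Shared fixtures, built once per test run and cached.
.fix <- new.env(parent = emptyenv())

fix_cached <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# a smooth band-limited random 16^3 volume at 1.5 A
fix_vol16 <- function() fix_cached("vol16", function() {
  set.seed(160)
  apply_shell_filter(volume(array(rnorm(16^3), rep(16, 3)), 1.5),
                     make_lowpass(6L, 16L))
})

# an unfiltered random 32^3 volume
fix_vol32 <- function() fix_cached("vol32", function() {
  set.seed(320)
  volume(array(rnorm(32^3), rep(32, 3)), 1.5)
})

# a blob phantom + mask at 24^3
fix_phantom24 <- function() fix_cached("phantom24", function() {
  make_phantom(phantom_spec(n = 24L, voxel_size = 1.5, n_blobs = 12L, seed = 77))
})

# a tiny perturbed (non-identity) denoiser for algebraic probes
fix_micro_model <- function() fix_cached("micro_model", function() {
  m <- build_model(denoiser_config(depth = 1L, base_channels = 2L,
                                   dropout_rate = 0, norm = "none",
                                   patch_edge = 4L), seed = 7)
  set.seed(71)
  pp <- blushr:::param_paths(m$params)
  for (p in pp) {
    v <- blushr:::tree_get(m$params, p)
    m$params <- blushr:::tree_set(m$params, p, v + rnorm(length(v)) * 0.05)
  }
  m
})

random_patch <- function(e, seed) {
  set.seed(seed)
  array(rnorm(e^3), rep(e, 3))
}

# the reference toy denoiser used by the refinement experiments (trained once
# per test run; 500 steps under the toy conditions)
fix_reference_model <- function() fix_cached("reference_model", function() {
  train_toy_denoiser(101, steps = 500L)$model
})
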