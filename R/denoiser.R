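#' Denoiser configuration
#'
#' Architecture of the residual volumetric U-net `f(v) = v + g(v)`: `depth`
#' encoder blocks (each conv 3x3x3 -> normalization -> SiLU, followed by 2x
#' average-pool downsampling), a bottleneck convolution block, and `depth`
#' decoder blocks (2x nearest-neighbor upsampling, skip concatenation, conv ->
#' normalization -> SiLU), closed by a zero-initialized 1x1x1 convolution so a
#' freshly built model is exactly the identity. Channel widths double per
#' level from `base_channels`. The reference configuration (depth 5,
#' `base_channels = 25`) lands near 13 million parameters; exact equality with
#' any particular published network is not claimed.
#'
#' Normalization defaults to instance normalization, which is insensitive to
#' mini-batch size; `norm = "none"` disables it.
#'
#' @param depth number of encoder/decoder levels (input edge must be divisible
#'   by `2^depth`).
#' @param base_channels channels at the first level.
#' @param dropout_rate dropout fraction applied after each block during
#'   training (reference 0.5).
#' @param norm `"instance"` or `"none"`.
#' @param patch_edge native patch edge (reference 64).
#' @param voxel_size the voxel size (Angstrom) the denoiser is trained at;
#'   1.5 gives the denoiser a 3 Angstrom Nyquist limit.
#' @export
denoiser_config <- function(depth = 5L, base_channels = 25L, dropout_rate = 0.5,
                            norm = c("instance", "none"), patch_edge = 64L,
                            voxel_size = 1.5) {
  norm <- match.arg(norm)
  if (depth < 1L) stop("depth must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("need 0 <= dropout_rate < 1")
  if (patch_edge %% 2^depth != 0) stop("patch_edge must be divisible by 2^depth")
  structure(list(depth = as.integer(depth), base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, norm = norm,
                 patch_edge = as.integer(patch_edge), voxel_size = voxel_size),
            class = "blush_denoiser_config")
}

channel_ladder <- function(config) config$base_channels * 2^(0:(config$depth - 1))

#' Build a denoiser model
#'
#' Initializes all trunk convolutions with He-scaled Gaussians and the final
#' 1x1x1 projection with zeros, so the freshly built residual model computes
#' the exact identity on any input.
#'
#' @param config a [denoiser_config()].
#' @param seed integer seed for the parameter draw.
#' @return A `blush_denoiser` (parameters + config + `training` flag).
#' @export
build_model <- function(config = denoiser_config(), seed = NULL) {
  with_seed(seed, {
    D <- config$depth; B <- config$base_channels
    ch <- channel_ladder(config)                      # C_1..C_D
    params <- list(enc = vector("list", D), dec = vector("list", D))
    norm_par <- function(c) if (config$norm == "instance")
      list(gamma = rep(1, c), beta = rep(0, c)) else NULL
    cin <- 1L
    for (d in seq_len(D)) {
      params$enc[[d]] <- c(list(W = init_conv(cin, ch[d]), b = rep(0, ch[d])),
                           norm_par(ch[d]))
      cin <- ch[d]
    }
    params$mid <- c(list(W = init_conv(ch[D], ch[D]), b = rep(0, ch[D])),
                    norm_par(ch[D]))
    for (d in seq(D, 1)) {
      cout <- if (d > 1) ch[d - 1] else B
      params$dec[[d]] <- c(list(W = init_conv(2L * ch[d], cout), b = rep(0, cout)),
                           norm_par(cout))
    }
    params$out <- list(W = matrix(0, B, 1), b = 0)    # zero-init: identity model
    structure(list(params = params, config = config, training = FALSE),
              class = "blush_denoiser")
  })
}

#' @export
print.blush_denoiser <- function(x, ...) {
  cat(sprintf("<blush_denoiser depth %d, base %d, %s norm, %s params>\n",
              x$config$depth, x$config$base_channels, x$config$norm,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `blush_denoiser`.
#' @export
count_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), as.double, 1))
}

# Forward pass on one (e,e,e) patch; returns y (+ cache when grad = TRUE).
model_forward <- function(model, x, training = FALSE, grad = FALSE) {
  cfg <- model$config; p <- model$params
  D <- cfg$depth
  e <- dim(x)[1]
  if (is.null(dim(x)) || length(dim(x)) != 3) stop("input patch must be a 3D array")
  if (e %% 2^D != 0) stop("patch edge ", e, " is not divisible by 2^depth")
  h <- array(x, c(dim(x), 1L))
  caches <- list(enc = vector("list", D), dec = vector("list", D))
  skips <- vector("list", D)
  for (d in seq_len(D)) {
    bf <- block_fwd(h, p$enc[[d]], cfg$norm, training, cfg$dropout_rate)
    skips[[d]] <- bf$y
    caches$enc[[d]] <- bf$cache
    h <- avgpool_fwd(bf$y)
  }
  bf <- block_fwd(h, p$mid, cfg$norm, training, cfg$dropout_rate)
  h <- bf$y; caches$mid <- bf$cache
  for (d in seq(D, 1)) {
    h <- upsample_fwd(h)
    h <- abind4(h, skips[[d]])
    bf <- block_fwd(h, p$dec[[d]], cfg$norm, training, cfg$dropout_rate)
    h <- bf$y; caches$dec[[d]] <- bf$cache
  }
  dm <- dim(h); V <- prod(dm[1:3])
  hm <- matrix(h, V, dm[4])
  res <- hm %*% p$out$W + p$out$b
  y <- x + array(res, dim(x))
  if (!grad) return(y)
  caches$final_h <- hm
  caches$dims <- dim(x)
  list(y = y, cache = caches)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Backward pass: grad of scalar loss wrt params given dL/dy.
model_backward <- function(model, gy, cache) {
  cfg <- model$config; p <- model$params
  D <- cfg$depth
  g <- list(enc = vector("list", D), dec = vector("list", D))
  V <- prod(cache$dims)
  gym <- matrix(gy, V, 1)
  # residual head: y = x + hm %*% W + b
  g$out <- list(dW = crossprod(cache$final_h, gym), db = sum(gym))
  gh <- array(gym %*% t(p$out$W), c(cache$dims, nrow(p$out$W)))
  for (d in seq_len(D)) {   # decoder blocks, innermost-last order is dec[1] first
    bb <- block_bwd(gh, p$dec[[d]], cache$dec[[d]], cfg$norm)
    g$dec[[d]] <- bb[c("dW", "db", "dgamma", "dbeta")]
    gx <- bb$gx
    cs <- dim(gx)[4] / 2
    g_skip <- gx[, , , cs + seq_len(cs), drop = FALSE]
    gh_up <- gx[, , , seq_len(cs), drop = FALSE]
    gh <- upsample_bwd(gh_up)
    # stash skip gradient to add after encoder path reaches this level
    g$dec[[d]]$g_skip <- g_skip
  }
  bb <- block_bwd(gh, p$mid, cache$mid, cfg$norm)
  g$mid <- bb[c("dW", "db", "dgamma", "dbeta")]
  gh <- bb$gx
  for (d in seq(D, 1)) {
    n_here <- dim(g$dec[[d]]$g_skip)[1]
    gy_enc <- avgpool_bwd(gh, n_here) + g$dec[[d]]$g_skip
    g$dec[[d]]$g_skip <- NULL
    bb <- block_bwd(gy_enc, p$enc[[d]], cache$enc[[d]], cfg$norm)
    g$enc[[d]] <- bb[c("dW", "db", "dgamma", "dbeta")]
    gh <- bb$gx
  }
  # gh is grad wrt the input patch; add the residual identity path if needed
  g$gx <- array(gh, cache$dims) + gy
  g
}

#' Apply the denoiser with recycling
#'
#' `recycle(model, y, r)` feeds the patch through the denoiser `r` times
#' (`r = 0` returns `y` unchanged); the training loss then applies the
#' denoiser once more to the result. Recycled passes run in inference mode
#' (no dropout) and are treated as constants by the gradient (no
#' backpropagation through recycling).
#'
#' @param model a `blush_denoiser`. @param y patch array.
#' @param r recycle count in `0..5`.
#' @export
recycle <- function(model, y, r) {
  if (r < 0 || r > 5) stop("r must be in 0..5")
  for (i in seq_len(r)) y <- model_forward(model, y, training = FALSE)
  y
}

#' Denoise a whole volume by patched inference
#'
#' Tiles the volume into overlapping patches; each patch is standardized,
#' passed once through the denoiser in inference mode, de-standardized with
#' its own pre-filter mean and standard deviation, and the patches are
#' blended back with partition-of-unity weights. Zero-variance patches pass
#' through unchanged.
#'
#' @param model a `blush_denoiser`.
#' @param v a [volume()] or 3D array.
#' @param patch_edge patch edge (default: the model's native edge).
#' @param overlap overlap between patches in voxels.
#' @export
denoise_volume <- function(model, v, patch_edge = NULL, overlap = NULL) {
  e <- as.integer(patch_edge %||% min(model$config$patch_edge, vol_edge(v)))
  ov <- as.integer(overlap %||% max(0L, min(e %/% 2L, vol_edge(v) - e)))
  if (vol_edge(v) == e) ov <- 0L
  grid <- tile_volume(v, e, ov)
  patches <- extract_patches(v, grid)
  out <- lapply(patches, function(pp) {
    m <- mean(pp); s <- sqrt(mean((pp - m)^2))
    if (!is.finite(s) || s < 1e-10) return(pp)
    m + s * model_forward(model, (pp - m) / s, training = FALSE)
  })
  stitch_patches(out, grid, template = if (is_volume(v)) v else NULL)
}

#' Save / load a denoiser checkpoint
#'
#' Single-file archive containing the parameters, configuration and a format
#' version.
#'
#' @param model a `blush_denoiser`. @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = 1L, config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format) || obj$format != 1L) stop("unrecognized checkpoint format")
  structure(list(params = obj$params, config = obj$config, training = FALSE),
            class = "blush_denoiser")
}
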