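# Minimal explicit-backprop layer zoo for the volumetric U-net. Tensors are
# (n1, n2, n3, C) arrays; conv3 primitives are compiled (see src/conv3.cpp).
# Each layer has a forward returning list(y, cache) and a backward taking
# (grad_y, cache) and returning grad_x plus parameter gradients.

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}
silu_bwd <- function(gy, cache) {
  s <- cache$s; x <- cache$x
  gy * (s * (1 + x * (1 - s)))
}

# per-channel normalization over the spatial dimensions of one sample
# (instance normalization; with single-sample processing this is also what a
# batch of one would give batch normalization)
instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); V <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, V, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(y, d), cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}
instnorm_bwd <- function(gy, cache) {
  d <- cache$d; V <- prod(d[1:3]); C <- d[4]
  gym <- matrix(gy, V, C)
  xhat <- cache$xhat
  dgamma <- colSums(gym * xhat)
  dbeta <- colSums(gym)
  gh <- sweep(gym, 2, cache$gamma, "*")
  gx <- sweep(gh - matrix(colMeans(gh), V, C, byrow = TRUE) -
                xhat * matrix(colMeans(gh * xhat), V, C, byrow = TRUE),
              2, cache$inv, "*")
  list(gx = array(gx, d), dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(x, rate) {
  if (rate <= 0) return(list(y = x, cache = NULL))
  mask <- array(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate), dim(x))
  list(y = x * mask, cache = mask)
}
dropout_bwd <- function(gy, cache) if (is.null(cache)) gy else gy * cache

# 2x average pooling and its adjoint-style companions
pool_idx <- function(n) list(a = seq(1L, n, by = 2L), b = seq(2L, n, by = 2L))
avgpool_fwd <- function(x) {
  d <- dim(x); i <- pool_idx(d[1]); j <- pool_idx(d[2]); k <- pool_idx(d[3])
  y <- (x[i$a, j$a, k$a, , drop = FALSE] + x[i$b, j$a, k$a, , drop = FALSE] +
        x[i$a, j$b, k$a, , drop = FALSE] + x[i$b, j$b, k$a, , drop = FALSE] +
        x[i$a, j$a, k$b, , drop = FALSE] + x[i$b, j$a, k$b, , drop = FALSE] +
        x[i$a, j$b, k$b, , drop = FALSE] + x[i$b, j$b, k$b, , drop = FALSE]) / 8
  y
}
avgpool_bwd <- function(gy, n) {
  rep2 <- rep(seq_len(n / 2), each = 2)
  gy[rep2, rep2, rep2, , drop = FALSE] / 8
}
upsample_fwd <- function(x) {
  n <- dim(x)[1]
  rep2 <- rep(seq_len(n), each = 2)
  x[rep2, rep2, rep2, , drop = FALSE]
}
upsample_bwd <- function(gy) avgpool_fwd(gy) * 8

# He-style initialization for a 3x3x3 conv
init_conv <- function(cin, cout) {
  array(rnorm(27 * cin * cout) * sqrt(2 / (27 * cin)), c(3, 3, 3, cin, cout))
}

# one conv->norm->SiLU(->dropout) block
block_fwd <- function(x, p, norm, training, dropout_rate) {
  h <- conv3_fwd(x, p$W, p$b)
  cache <- list(x = x)
  if (norm == "instance") {
    nf <- instnorm_fwd(h, p$gamma, p$beta)
    h <- nf$y; cache$norm <- nf$cache
  }
  af <- silu_fwd(h)
  h <- af$y; cache$act <- af$cache
  if (training && dropout_rate > 0) {
    df <- dropout_fwd(h, dropout_rate)
    h <- df$y; cache$drop <- df$cache
  }
  list(y = h, cache = cache)
}
block_bwd <- function(gy, p, cache, norm) {
  if (!is.null(cache$drop)) gy <- dropout_bwd(gy, cache$drop)
  gy <- silu_bwd(gy, cache$act)
  grads <- list()
  if (norm == "instance") {
    nb <- instnorm_bwd(gy, cache$norm)
    gy <- nb$gx; grads$dgamma <- nb$dgamma; grads$dbeta <- nb$dbeta
  }
  wb <- conv3_bwd_weights(cache$x, gy)
  grads$dW <- wb$w; grads$db <- wb$b
  grads$gx <- conv3_bwd_input(gy, p$W)
  grads
}
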