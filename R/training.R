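# Recycling loss and optimizer. The loss over a mini-batch of b half-map
# pairs, each contributing both half directions k in {0,1}, is
#   L = (1/2b) sum_i sum_k || ybar_i^(k) - f( R_r[f, y_i^(k)] ) ||^2
# with ||.||^2 the sum of squared voxel differences over the patch. Recycled
# passes run in inference mode and are not differentiated; only the final
# denoiser application carries gradients (and dropout, during training).

# ---- parameter tree walking -------------------------------------------------

param_paths <- function(params) {
  out <- list()
  walk <- function(node, path) {
    for (nm in names(node)) {
      child <- node[[nm]]
      if (is.list(child)) {
        if (nm %in% c("enc", "dec")) {
          for (i in seq_along(child)) walk(child[[i]], c(path, list(nm, i)))
        } else {
          walk(child, c(path, list(nm)))
        }
      } else if (is.numeric(child) && nm %in% c("W", "b", "gamma", "beta")) {
        out[[length(out) + 1L]] <<- c(path, list(nm))
      }
    }
  }
  walk(params, list())
  out
}

tree_get <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}
tree_set <- function(tree, path, value) {
  if (length(path) == 1L) { tree[[path[[1]]]] <- value; return(tree) }
  tree[[path[[1]]]] <- tree_set(tree[[path[[1]]]], path[-1], value)
  tree
}
grad_path <- function(path) {
  n <- length(path)
  path[[n]] <- paste0("d", path[[n]])
  path
}

# ---- loss -------------------------------------------------------------------

#' Training example container
#'
#' @param y,ybar standardized patch arrays of identical shape.
#' @param r recycle count in `0..5`.
#' @param id identifier.
#' @export
training_example <- function(y, ybar, r = 0L, id = "ex") {
  if (!identical(dim(y), dim(ybar))) stop("y and ybar must have identical shape")
  structure(list(y = y, ybar = ybar, r = as.integer(r), id = id),
            class = "blush_training_example")
}

#' Recycling loss over a batch
#'
#' Evaluates the mean-squared recycling loss (inference mode, deterministic).
#' The batch is a list of training examples; each pair of half-directions
#' counts as one sample, so the normalization is `1 / (2 * length(batch) / 2)`.
#'
#' @param model a `blush_denoiser`. @param batch list of examples.
#' @return Non-negative scalar.
#' @export
compute_loss <- function(model, batch) {
  b <- length(batch) / 2
  tot <- 0
  for (ex in batch) {
    yr <- recycle(model, ex$y, ex$r)
    f <- model_forward(model, yr, training = FALSE)
    if (!identical(dim(f), dim(ex$ybar))) stop("shape mismatch between output and target")
    tot <- tot + sum((ex$ybar - f)^2)
  }
  tot / (2 * b)
}

# Loss plus parameter gradients (the differentiated pass optionally with
# dropout active). Returns list(loss, grads) with grads matching param_paths.
loss_and_grads <- function(model, batch, training = TRUE) {
  b <- length(batch) / 2
  paths <- param_paths(model$params)
  acc <- NULL
  tot <- 0
  for (ex in batch) {
    yr <- recycle(model, ex$y, ex$r)
    fw <- model_forward(model, yr, training = training, grad = TRUE)
    resid <- fw$y - ex$ybar
    tot <- tot + sum(resid^2)
    # dL/dy for this example: 2 * resid / (2b) = resid / b
    g <- model_backward(model, resid / b, fw$cache)
    if (is.null(acc)) {
      acc <- lapply(paths, function(p) tree_get(g, grad_path(p)))
    } else {
      for (i in seq_along(paths))
        acc[[i]] <- acc[[i]] + tree_get(g, grad_path(paths[[i]]))
    }
  }
  list(loss = tot / (2 * b), grads = acc, paths = paths)
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(paths, params) {
  lapply(paths, function(p) {
    v <- tree_get(params, p)
    list(m = v * 0, v = v * 0)
  })
}

adam_step <- function(params, paths, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(paths)) {
    g <- grads[[i]]
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p <- tree_get(params, paths[[i]]) - lr * mhat / (sqrt(vhat) + eps)
    params <- tree_set(params, paths[[i]], p)
    state[[i]] <- st
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param steps number of optimization steps.
#' @param batch_size pairs per mini-batch (reference 8); each pair contributes
#'   both half directions.
#' @param lr peak Adam learning rate, decayed to `lr_min` on a cosine schedule.
#' @param lr_min final learning rate.
#' @param seed integer seed governing all randomness of the run.
#' @param checkpoint_every emit a checkpoint every this many steps (0 = never).
#' @param checkpoint_dir directory for checkpoints.
#' @export
training_config <- function(steps, batch_size = 8L, lr = 1e-3, lr_min = 1e-5,
                            seed = 1L, checkpoint_every = 0L, checkpoint_dir = NULL) {
  if (steps < 1L || batch_size < 1L) stop("steps and batch_size must be >= 1")
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 lr = lr, lr_min = lr_min, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "blush_training_config")
}

#' Train a denoiser on a corpus of half-map pairs
#'
#' Per step: sample `batch_size` pairs with replacement, build one augmented
#' example per half direction (fresh random filters, transform, noise and
#' recycle count each draw), run the recycling loss with dropout active in the
#' differentiated pass, and take one Adam step on a cosine-decayed learning
#' rate. The loss trace is deterministic under a fixed seed and thread
#' configuration. A non-finite loss aborts the run, returning the last good
#' parameters.
#'
#' @param corpus list of [halfmap_pair()]s.
#' @param model a freshly built (or resumed) `blush_denoiser`.
#' @param cfg a [training_config()].
#' @param policy an [augmentation_policy()]; its `patch_edge` must be
#'   divisible by `2^depth` of the model.
#' @return `list(model, trace)` where `trace` is a data.frame with `step`,
#'   `loss`, `lr`.
#' @export
train_denoiser <- function(corpus, model, cfg, policy = augmentation_policy()) {
  if (length(corpus) == 0) stop("corpus is empty")
  set.seed(cfg$seed)
  paths <- param_paths(model$params)
  state <- adam_init(paths, model$params)
  trace <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  last_good <- model$params
  for (t in seq_len(cfg$steps)) {
    idx <- sample.int(length(corpus), cfg$batch_size, replace = TRUE)
    batch <- list()
    for (i in idx) {
      for (k in 0:1) {
        ex <- build_example(corpus[[i]], k, seed = NULL, policy = policy)
        batch[[length(batch) + 1L]] <- ex
      }
    }
    lg <- loss_and_grads(model, batch, training = TRUE)
    if (!is.finite(lg$loss)) {
      warning("non-finite loss at step ", t, "; aborting with last good parameters")
      model$params <- last_good
      break
    }
    last_good <- model$params
    lr_t <- cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) * (1 + cos(pi * (t - 1) / cfg$steps))
    upd <- adam_step(model$params, paths, lg$grads, state, t, lr_t)
    model$params <- upd$params
    state <- upd$state
    trace <- rbind(trace, data.frame(step = t, loss = lg$loss, lr = lr_t))
    if (cfg$checkpoint_every > 0 && t %% cfg$checkpoint_every == 0 &&
        !is.null(cfg$checkpoint_dir)) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_model(model, file.path(cfg$checkpoint_dir, sprintf("ckpt_%06d.rds", t)))
    }
  }
  list(model = model, trace = trace)
}
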