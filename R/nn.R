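# Minimal explicit-gradient layer library: 3D convolution (Rcpp im2col+GEMM),
# 2D convolution, LeakyReLU/tanh/sigmoid, BatchNorm over a sample list, Adam,
# and tree utilities over nested parameter lists (leaves = numeric arrays).

conv3d_fw <- function(x, w, b, stride = 1L, pad = 1L) {
  k <- dim(w)[1]
  if (k == 3L && stride == 1L && pad == 1L)
    conv3s1_fw_cpp(x, dim(x), w, b)
  else if (k == 4L && stride == 2L && pad == 1L && all(dim(x)[1:3] %% 2L == 0L))
    conv4s2_fw_cpp(x, dim(x), w, b)
  else
    conv3d_fw_cpp(x, dim(x), w, dim(w), b, as.integer(stride), as.integer(pad))
}

conv3d_bw <- function(x, w, gy, stride = 1L, pad = 1L, need_gx = TRUE) {
  k <- dim(w)[1]
  if (k == 3L && stride == 1L && pad == 1L)
    conv3s1_bw_cpp(x, dim(x), w, gy, need_gx)
  else if (k == 4L && stride == 2L && pad == 1L && all(dim(x)[1:3] %% 2L == 0L))
    conv4s2_bw_cpp(x, dim(x), w, gy, need_gx)
  else
    conv3d_bw_cpp(x, dim(x), w, dim(w), gy, as.integer(stride),
                  as.integer(pad), need_gx)
}

lrelu_fw <- function(x, slope = 0.2) lrelu_fw_cpp(x, slope)
lrelu_bw <- function(x, g, slope = 0.2) lrelu_bw_cpp(x, g, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

# 2D "same" 3x3 convolution on [H, W, Cin] -> [H, W, Cout], zero padding.
conv2d_fw <- function(x, w, b) conv2d_fw_cpp(x, dim(x), w, b)

conv2d_bw <- function(x, w, gy) conv2d_bw_cpp(x, dim(x), w, dim(w), gy)

# BatchNorm over a list of [D,H,W,C] arrays (stats pooled over batch and
# space, per channel). Returns normalized list, cache for backward, and
# updated running moments.
bn_fw <- function(xs, gamma, beta, rm, rv, train, momentum = 0.1, eps = 1e-5) {
  C <- length(gamma)
  if (train) {
    n <- 0; s1 <- numeric(C); s2 <- numeric(C)
    for (x in xs) {
      mom <- channel_moments_cpp(x, C)
      n <- n + mom$n
      s1 <- s1 + mom$s1
      s2 <- s2 + mom$s2
    }
    mu <- s1 / n
    var <- pmax(s2 / n - mu^2, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * var
  } else {
    mu <- rm; var <- rv; n <- NA_real_
  }
  inv <- 1 / sqrt(var + eps)
  xhat <- lapply(xs, function(x) channel_affine_cpp(x, inv, -mu * inv))
  ys <- lapply(xhat, function(xh) channel_affine_cpp(xh, gamma, beta))
  list(ys = ys, cache = list(xhat = xhat, inv = inv, gamma = gamma,
                             n = n, train = train),
       rm = rm, rv = rv)
}

bn_bw <- function(cache, gys) {
  C <- length(cache$gamma)
  ggamma <- numeric(C); gbeta <- numeric(C)
  for (i in seq_along(gys)) {
    d <- channel_dots_cpp(gys[[i]], cache$xhat[[i]], C)
    ggamma <- ggamma + d$sum_gx
    gbeta <- gbeta + d$sum_g
  }
  k <- cache$gamma * cache$inv
  gxs <- if (isTRUE(cache$train)) {
    n <- cache$n
    lapply(seq_along(gys), function(i)
      bn_bw_train_cpp(gys[[i]], cache$xhat[[i]], k, gbeta / n, ggamma / n))
  } else {
    lapply(gys, function(g) channel_affine_cpp(g, k, numeric(C)))
  }
  list(gxs = gxs, ggamma = ggamma, gbeta = gbeta)
}

# ---- parameter-tree utilities -----------------------------------------------

tree_map <- function(f, tree, ...) {
  if (is.list(tree)) {
    out <- lapply(tree, function(x) tree_map(f, x, ...))
    names(out) <- names(tree)
    out
  } else f(tree, ...)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_zero_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

# Visit leaves with their names (used by init_weights).
tree_walk_named <- function(tree, f) {
  stopifnot(is.list(tree))
  for (nm in names(tree)) {
    if (is.list(tree[[nm]])) tree[[nm]] <- tree_walk_named(tree[[nm]], f)
    else tree[[nm]] <- f(nm, tree[[nm]])
  }
  tree
}

#' Initialize network weights
#'
#' Draws every convolution weight i.i.d. from N(0, std^2); biases are zeroed,
#' BatchNorm scale/shift are reset to 1/0. Deterministic given the R RNG
#' state (call `set.seed()` first for reproducibility).
#'
#' @param params nested parameter list (as built by [generator_init()] /
#'   [discriminator_init()]): leaf names starting with `w` are weights, `b`
#'   biases, `gamma`/`beta` BatchNorm affine terms.
#' @param std standard deviation of the weight prior, default 0.02.
#' @return The parameter tree with re-drawn values.
#' @export
init_weights <- function(params, std = 0.02) {
  stopifnot(std > 0)
  tree_walk_named(params, function(nm, leaf) {
    if (startsWith(nm, "w")) {
      v <- rnorm(length(leaf), 0, std); dim(v) <- dim(leaf)
      if (is.null(dim(leaf))) v <- as.numeric(v)
      v
    } else if (startsWith(nm, "b")) leaf * 0
    else if (nm == "gamma") leaf * 0 + 1
    else if (nm == "beta") leaf * 0
    else leaf
  })
}

adam_init <- function(params) {
  list(m = tree_zero_like(params), v = tree_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.5, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
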