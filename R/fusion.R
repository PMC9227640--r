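# Tanh-normalized Hadamard fusion of view feature maps, the attention-like
# mixing step: g(i,j) = tanh(x(i,j) * y'(i,j)) / sum_i' tanh(x(i',j) * y'(i',j)),
# where y' is the matrix transpose of y and the sum runs down each column.
# The third view enters by the same rule applied to (g, z). A small epsilon,
# carrying the sign of the column sum, guards the normalizer against
# cancellation; columns therefore sum to ~1 whenever the normalizer is
# well-conditioned. Unlike a softmax, the tanh is not scale-invariant:
# rescaling the inputs changes the output.

fuse_pair_fw <- function(x, y, eps = 1e-8) {
  prod <- x * t(y)
  tt <- tanh(prod)
  s <- colSums(tt)
  sgn <- ifelse(s >= 0, 1, -1)
  denom <- s + eps * sgn
  g <- sweep(tt, 2, denom, "/")
  list(g = g, cache = list(x = x, y = y, tt = tt, denom = denom))
}

fuse_pair_bw <- function(cache, gg) {
  tt <- cache$tt; denom <- cache$denom
  # d g_ij / d t_kj = delta_ik / denom_j - t_ij / denom_j^2
  col_dot <- colSums(gg * tt)
  gt <- sweep(sweep(gg, 2, denom, "/"), 2, col_dot / denom^2, "-")
  gprod <- gt * (1 - tt^2)
  gx <- gprod * t(cache$y)
  gy <- t(gprod * cache$x)
  list(gx = gx, gy = gy)
}

#' Fuse two view feature maps
#'
#' Elementwise product of `x` with the transpose of `y`, squashed by tanh
#' and normalized down each column (see the module notes above).
#'
#' @param x,y square feature maps of equal size.
#' @param eps normalizer guard, added with the sign of the column sum.
#' @return Fused c x c map whose columns sum to ~1 when well-conditioned.
#' @export
fuse_pair <- function(x, y, eps = 1e-8) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (!all(dim(x) == dim(y)) || nrow(x) != ncol(x))
    stop("fuse_pair expects equal square maps, got ",
         paste(dim(x), collapse = "x"), " and ", paste(dim(y), collapse = "x"))
  fuse_pair_fw(x, y, eps)$g
}

#' Fuse the three view feature maps
#'
#' Two-stage fusion: `g = fuse_pair(x, y)`, then `l` from `(g, z)` by the
#' same tanh-normalized Hadamard rule.
#'
#' @param x,y,z square feature maps of equal size (sagittal, coronal, axial).
#' @param eps normalizer guard.
#' @return List of class `fused_map` with elements `g` and `l`.
#' @export
fuse_triple <- function(x, y, z, eps = 1e-8) {
  g <- fuse_pair(x, y, eps)
  l <- fuse_pair(g, z, eps)
  structure(list(g = g, l = l), class = "fused_map")
}

fuse_triple_fw <- function(x, y, z, eps = 1e-8) {
  s1 <- fuse_pair_fw(x, y, eps)
  s2 <- fuse_pair_fw(s1$g, z, eps)
  list(g = s1$g, l = s2$g, cache = list(s1 = s1$cache, s2 = s2$cache))
}

fuse_triple_bw <- function(cache, gl) {
  b2 <- fuse_pair_bw(cache$s2, gl)
  b1 <- fuse_pair_bw(cache$s1, b2$gx)
  list(gx = b1$gx, gy = b1$gy, gz = b2$gy)
}
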