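# Fixed 3x3x3 Sobel operator: the outer product of the smoothing profile
# [1,2,1] on two axes with the central-difference profile [1,0,-1] on the
# derivative axis. The z kernel's slice at offset -1 is [[1,2,1],[2,4,2],
# [1,2,1]], the central slice is zero, and the +1 slice is its negation;
# x and y kernels are axis permutations of the same separable construction.

#' Construct a 3x3x3 Sobel kernel
#'
#' @param axis derivative axis, one of `"x"`, `"y"`, `"z"` (array dims 1-3).
#' @return An object of class `sobel_kernel`: list with `axis` and the 3x3x3
#'   `weights` array (entries sum to zero; antisymmetric along the derivative
#'   axis, symmetric along the two smoothing axes).
#' @export
sobel_kernel <- function(axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  s <- c(1, 2, 1)     # smoothing profile
  d <- c(1, 0, -1)    # derivative profile at offsets (-1, 0, +1)
  w <- switch(axis,
    x = outer(d, outer(s, s)),
    y = outer(s, outer(d, s)),
    z = outer(s, outer(s, d)))
  dim(w) <- c(3L, 3L, 3L)
  structure(list(axis = axis, weights = w), class = "sobel_kernel")
}

# 1D 3-tap cross-correlation along one axis with reflected (half-sample
# symmetric) boundaries: out[i] = t[1] x[i-1] + t[2] x[i] + t[3] x[i+1].
corr1d_reflect <- function(arr, axis, taps) {
  n <- dim(arr)[axis]
  idx_m <- c(1L, seq_len(n - 1L))
  idx_p <- c(seq_len(n - 1L) + 1L, n)
  pick <- function(idx) {
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- idx
    do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  taps[1] * pick(idx_m) + taps[2] * arr + taps[3] * pick(idx_p)
}

# Directional Sobel response (cross-correlation with the axis kernel),
# computed separably. Reflection padding keeps the output on the input grid.
sobel_response <- function(x, axis) {
  s <- c(1, 2, 1); d <- c(1, 0, -1)
  for (a in 1:3) x <- corr1d_reflect(x, a, if (a == axis) d else s)
  x
}

#' 3D Sobel gradient magnitude
#'
#' Applies the three directional 3x3x3 Sobel kernels by cross-correlation
#' with reflection padding and returns the per-voxel gradient magnitude
#' `sqrt(Gx^2 + Gy^2 + Gz^2)`. This is the geometric channel fed to the
#' generator's decoder: it is zero over locally constant tissue and peaks at
#' tissue boundaries.
#'
#' @param v volume or 3D array, at least 3 voxels along every axis.
#' @return Volume of non-negative gradient magnitudes, same shape as input.
#' @export
apply_sobel <- function(v) {
  v <- as_volume(v)
  x <- v$data
  g2 <- sobel_response(x, 1L)^2 + sobel_response(x, 2L)^2 +
    sobel_response(x, 3L)^2
  v$data <- sqrt(g2)
  v
}
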