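# Per-view separable-convolution encoder ("Elicit" encoder). Each anatomical
# view collapses its own axis of the PET volume to a c x c feature map via
# two parallel separable branches:
#   branch A: one axis-spanning separable convolution (extent E -> 1),
#             capturing long-range dependencies along the view axis;
#   branch B: a separable convolution of extent E/2 with stride E/2
#             (E -> 2 positions) followed by a length-2 convolution (2 -> 1),
#             capturing local dependencies.
# Branch outputs are concatenated as channels of the 2D map and mixed by two
# 3x3 "same" 2D convolutions down to a single-channel c x c map (c = E).
# LeakyReLU(0.2) follows every convolution.

#' Encoder configuration
#'
#' @param volume_extent cubic volume side E (also the feature-map side c).
#' @param local_kernel extent of the local separable branch (default E/2).
#' @param channels_a,channels_b channels of the long-range / local branches.
#' @param channels_2d hidden channels of the 2D mixing convolutions.
#' @param eps numerical guard added (with the sign of the sum) to the fusion
#'   normalizer.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(volume_extent = 90L, local_kernel = NULL,
                           channels_a = 2L, channels_b = 2L,
                           channels_2d = 4L, eps = 1e-8) {
  volume_extent <- as.integer(volume_extent)
  if (is.null(local_kernel)) local_kernel <- volume_extent %/% 2L
  local_kernel <- as.integer(local_kernel)
  stopifnot(volume_extent >= 4L, local_kernel <= volume_extent,
            2L * local_kernel == volume_extent, eps > 0)
  structure(list(volume_extent = volume_extent, long_kernel = volume_extent,
                 local_kernel = local_kernel, channels_a = channels_a,
                 channels_b = channels_b, channels_2d = channels_2d,
                 c = volume_extent, eps = eps),
            class = "encoder_config")
}

encoder_view_init <- function(cfg) {
  E <- cfg$volume_extent; L <- cfg$local_kernel
  cA <- cfg$channels_a; cB <- cfg$channels_b; c2 <- cfg$channels_2d
  list(
    wA = array(0, c(E, cA)), bA = numeric(cA),
    wB1 = array(0, c(L, cB)), bB1 = numeric(cB),
    wB2 = array(0, c(2L, cB, cB)), bB2 = numeric(cB),
    wc1 = array(0, c(3L, 3L, cA + cB, c2)), bc1 = numeric(c2),
    wc2 = array(0, c(3L, 3L, c2, 1L)), bc2 = numeric(1L))
}

encoder_init <- function(cfg) {
  list(x = encoder_view_init(cfg), y = encoder_view_init(cfg),
       z = encoder_view_init(cfg))
}

# Forward for one view. X: E x n matrix (collapse axis first), n = c1*c2.
encode_view_fw <- function(X, p, cfg) {
  E <- cfg$volume_extent; L <- cfg$local_kernel
  n <- ncol(X); side <- as.integer(sqrt(n))
  a0 <- crossprod(X, p$wA)
  a0 <- sweep(a0, 2, p$bA, "+")
  a1 <- lrelu_fw(a0)
  X1 <- X[seq_len(L), , drop = FALSE]
  X2 <- X[L + seq_len(L), , drop = FALSE]
  b0_1 <- sweep(crossprod(X1, p$wB1), 2, p$bB1, "+")
  b0_2 <- sweep(crossprod(X2, p$wB1), 2, p$bB1, "+")
  b1_1 <- lrelu_fw(b0_1); b1_2 <- lrelu_fw(b0_2)
  c0 <- b1_1 %*% p$wB2[1, , ] + b1_2 %*% p$wB2[2, , ]
  c0 <- sweep(c0, 2, p$bB2, "+")
  c1 <- lrelu_fw(c0)
  feat <- array(cbind(a1, c1), c(side, side, cfg$channels_a + cfg$channels_b))
  f0 <- conv2d_fw(feat, p$wc1, p$bc1)
  f1 <- lrelu_fw(f0)
  g0 <- conv2d_fw(f1, p$wc2, p$bc2)
  g1 <- lrelu_fw(g0)
  list(map = g1[, , 1],
       cache = list(X = X, a0 = a0, b0_1 = b0_1, b0_2 = b0_2,
                    b1_1 = b1_1, b1_2 = b1_2, c0 = c0, feat = feat,
                    f0 = f0, f1 = f1, g0 = g0, side = side))
}

encode_view_bw <- function(gmap, p, cache, cfg) {
  L <- cfg$local_kernel
  side <- cache$side
  gg0 <- lrelu_bw(cache$g0, array(gmap, c(side, side, 1L)))
  r2 <- conv2d_bw(cache$f1, p$wc2, gg0)
  gf0 <- lrelu_bw(cache$f0, r2$gx)
  r1 <- conv2d_bw(cache$feat, p$wc1, gf0)
  cA <- cfg$channels_a; cB <- cfg$channels_b
  gfeat <- matrix(r1$gx, ncol = cA + cB)
  ga1 <- gfeat[, seq_len(cA), drop = FALSE]
  gc1 <- gfeat[, cA + seq_len(cB), drop = FALSE]
  ga0 <- lrelu_bw(cache$a0, ga1)
  gwA <- cache$X %*% ga0
  gbA <- colSums(ga0)
  gc0 <- lrelu_bw(cache$c0, gc1)
  gbB2 <- colSums(gc0)
  gwB2 <- array(0, dim(p$wB2))
  gwB2[1, , ] <- crossprod(cache$b1_1, gc0)
  gwB2[2, , ] <- crossprod(cache$b1_2, gc0)
  gb1_1 <- gc0 %*% t(p$wB2[1, , ])
  gb1_2 <- gc0 %*% t(p$wB2[2, , ])
  gb0_1 <- lrelu_bw(cache$b0_1, gb1_1)
  gb0_2 <- lrelu_bw(cache$b0_2, gb1_2)
  X1 <- cache$X[seq_len(L), , drop = FALSE]
  X2 <- cache$X[L + seq_len(L), , drop = FALSE]
  gwB1 <- X1 %*% gb0_1 + X2 %*% gb0_2
  gbB1 <- colSums(gb0_1) + colSums(gb0_2)
  list(wA = gwA, bA = gbA, wB1 = gwB1, bB1 = gbB1, wB2 = gwB2, bB2 = gbB2,
       wc1 = r1$gw, bc1 = r1$gb, wc2 = r2$gw, bc2 = r2$gb)
}

view_matrix <- function(v, axis) {
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  matrix(aperm(v, perm), d[axis], prod(d[-axis]))
}

#' Encode a PET volume into three view feature maps
#'
#' Runs the separable-convolution encoder on the sagittal (x), coronal (y)
#' and axial (z) views, collapsing the corresponding array axis of the
#' volume. Volumes are stored RAS: axis 1 = x (sagittal), 2 = y (coronal),
#' 3 = z (axial).
#'
#' @param v preprocessed volume (cubic, side `cfg$volume_extent`).
#' @param params encoder parameter tree (element `enc` of
#'   [generator_init()]'s params, or [init_weights()] on the skeleton).
#' @param cfg [encoder_config()].
#' @return List with `x`, `y`, `z`: the three c x c feature maps.
#' @export
encode_views <- function(v, params, cfg) {
  x <- if (is.array(v) && length(dim(v)) == 3L) v else vol_data(v)
  if (!all(dim(x) == cfg$volume_extent))
    stop("encoder expects a ", cfg$volume_extent, "^3 volume, got ",
         paste(dim(x), collapse = "x"))
  fx <- encode_view_fw(view_matrix(x, 1L), params$x, cfg)
  fy <- encode_view_fw(view_matrix(x, 2L), params$y, cfg)
  fz <- encode_view_fw(view_matrix(x, 3L), params$z, cfg)
  structure(list(x = fx$map, y = fy$map, z = fz$map,
                 cache = list(x = fx$cache, y = fy$cache, z = fz$cache)),
            class = "view_feature_maps")
}
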