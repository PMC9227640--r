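# Generator and discriminator.
#
# Generator: separable-conv encoder -> tanh-Hadamard fusion -> a two-channel
# 3D decoder input (channel 1: the fused c x c map tiled along the axial
# axis; channel 2: the Sobel gradient-magnitude volume passed through a
# learnable 3x3x3 convolution that fixes the edge scale) -> four 3x3x3
# convolution layers (BatchNorm + LeakyReLU(0.2) after the first three),
# final tanh so outputs live in (-1, 1).
#
# Discriminator: conditional 3D fully convolutional classifier over the
# (pet, candidate-mri) channel pair: four 4x4x4 stride-2 convolutions with
# LeakyReLU(0.2), a 1x1x1 projection, global average, sigmoid.

#' Initialize generator parameters
#'
#' Builds the parameter tree (encoder, post-Sobel convolution, decoder) and
#' draws weights from N(0, `cfg$init_std`^2) via [init_weights()]. BatchNorm
#' running moments live alongside in `$bn`.
#'
#' @param cfg an [egan_config()].
#' @return List with `params` (trainable tree) and `bn` (running stats).
#' @export
generator_init <- function(cfg) {
  ch <- c(2L, cfg$dec_channels, 1L)
  dec <- list()
  for (i in seq_len(4L)) {
    # BatchNorm follows layers 1-3, so a conv bias there would be redundant
    # (absorbed by the batch mean); beta plays that role instead.
    lay <- if (i < 4L)
      list(w = array(0, c(3L, 3L, 3L, ch[i], ch[i + 1])),
           gamma = rep(1, ch[i + 1]), beta = numeric(ch[i + 1]))
    else
      list(w = array(0, c(3L, 3L, 3L, ch[i], ch[i + 1])),
           b = numeric(ch[i + 1]))
    dec[[paste0("l", i)]] <- lay
  }
  params <- list(
    enc = encoder_init(cfg$enc),
    post = list(w = array(0, c(3L, 3L, 3L, 1L, 1L)), b = numeric(1L)),
    dec = dec)
  bn <- lapply(seq_len(3L), function(i)
    list(rm = numeric(ch[i + 1]), rv = rep(1, ch[i + 1])))
  list(params = init_weights(params, cfg$init_std), bn = bn)
}

#' Initialize discriminator parameters
#'
#' @param cfg an [egan_config()].
#' @return List with `params`: four stride-2 4x4x4 convolution layers plus a
#'   1x1x1 projection head.
#' @export
discriminator_init <- function(cfg) {
  ch <- c(2L, cfg$disc_channels)
  layers <- list()
  for (i in seq_len(4L)) {
    layers[[paste0("l", i)]] <-
      list(w = array(0, c(4L, 4L, 4L, ch[i], ch[i + 1])),
           b = numeric(ch[i + 1]))
  }
  layers$head <- list(w = array(0, c(1L, 1L, 1L, ch[5], 1L)),
                      b = numeric(1L))
  list(params = init_weights(layers, cfg$init_std))
}

#' Assemble the two-channel decoder input
#'
#' Channel 1 is the fused feature map `l` tiled along the axial axis to the
#' volume grid (the minimal-parameter bridge from the 2D representation back
#' to 3D); channel 2 is the Sobel edge volume passed through the learnable
#' post-Sobel 3x3x3 convolution.
#'
#' @param fused a [fuse_triple()] result (uses `$l`).
#' @param edge the Sobel gradient-magnitude volume (array or volume), or
#'   `NULL` to ablate the geometric channel (channel 2 zeroed).
#' @param post_params list with the post-Sobel conv `w` (3x3x3x1x1) and `b`.
#' @param extent cubic volume side; must equal the fused map side.
#' @return 4D array `extent^3 x 2`.
#' @export
assemble_decoder_input <- function(fused, edge, post_params, extent) {
  l <- fused$l
  if (nrow(l) != extent)
    stop("fused map side ", nrow(l), " does not match volume extent ", extent)
  x <- array(0, c(extent, extent, extent, 2L))
  x[, , , 1L] <- array(l, c(extent, extent, extent))  # tile along axial axis
  if (!is.null(edge)) {
    e <- if (is.array(edge) && length(dim(edge)) == 3L) edge else vol_data(edge)
    x[, , , 2L] <- conv3d_fw(array(e, c(dim(e), 1L)), post_params$w,
                             post_params$b, stride = 1L, pad = 1L)
  }
  x
}

# Full generator forward over a batch (lists of E^3 arrays). Returns outputs
# and, for training, the caches needed by generator_backward plus updated BN
# running stats.
generator_forward_batch <- function(pets, edges, gen, cfg, train = FALSE,
                                    ablate_sobel = FALSE) {
  E <- cfg$extent
  B <- length(pets)
  p <- gen$params
  enc_out <- vector("list", B); fus <- vector("list", B)
  x0 <- vector("list", B)
  for (b in seq_len(B)) {
    enc_out[[b]] <- encode_views(pets[[b]], p$enc, cfg$enc)
    fus[[b]] <- fuse_triple_fw(enc_out[[b]]$x, enc_out[[b]]$y,
                               enc_out[[b]]$z, cfg$enc$eps)
    x0[[b]] <- assemble_decoder_input(
      fus[[b]], if (ablate_sobel) NULL else edges[[b]], p$post, E)
  }
  h <- x0
  caches <- list(enc = enc_out, fus = fus, x0 = x0,
                 edges = if (ablate_sobel) NULL else edges, lay = list())
  bn <- gen$bn
  momentum <- 0.1
  for (i in seq_len(3L)) {
    C <- length(p$dec[[i]]$gamma)
    pre <- lapply(h, function(x) conv3d_fw(x, p$dec[[i]]$w, numeric(C)))
    if (train) {
      n <- 0; s1 <- numeric(C); s2 <- numeric(C)
      for (x in pre) {
        mom <- channel_moments_cpp(x, C)
        n <- n + mom$n; s1 <- s1 + mom$s1; s2 <- s2 + mom$s2
      }
      mu <- s1 / n
      var <- pmax(s2 / n - mu^2, 0)
      bn[[i]]$rm <- (1 - momentum) * bn[[i]]$rm + momentum * mu
      bn[[i]]$rv <- (1 - momentum) * bn[[i]]$rv + momentum * var
    } else {
      mu <- bn[[i]]$rm; var <- bn[[i]]$rv; n <- NA_real_
    }
    inv <- 1 / sqrt(var + 1e-5)
    fa <- lapply(pre, function(x)
      bn_act_fw_cpp(x, mu, inv, p$dec[[i]]$gamma, p$dec[[i]]$beta, 0.2))
    acts <- lapply(fa, `[[`, "act")
    caches$lay[[i]] <- list(x = h, xhat = lapply(fa, `[[`, "xhat"),
                            act = acts, inv = inv, n = n, train = train)
    h <- acts
  }
  pre4 <- lapply(h, function(x) conv3d_fw(x, p$dec$l4$w, p$dec$l4$b))
  out <- lapply(pre4, function(x) { y <- tanh(x); dim(y) <- rep(E, 3L); y })
  caches$lay[[4]] <- list(x = h, pre = pre4)
  caches$out <- out
  list(out = out, cache = caches, bn = bn)
}

# Backward: gouts is a list of E^3 arrays (dLoss/dOutput). Returns the
# gradient tree matching gen$params.
generator_backward_batch <- function(gouts, gen, cache, cfg,
                                     ablate_sobel = FALSE) {
  E <- cfg$extent
  B <- length(gouts)
  p <- gen$params
  grads <- tree_zero_like(p)
  # layer 4 (conv + tanh)
  l4 <- cache$lay[[4]]
  g <- vector("list", B)
  for (b in seq_len(B)) {
    o <- cache$out[[b]]
    gt <- gouts[[b]] * (1 - o^2)
    dim(gt) <- c(E, E, E, 1L)
    r <- conv3d_bw(l4$x[[b]], p$dec$l4$w, gt)
    grads$dec$l4$w <- grads$dec$l4$w + r$gw
    grads$dec$l4$b <- grads$dec$l4$b + r$gb
    g[[b]] <- r$gx
  }
  # layers 3..1 (conv + BN + LeakyReLU, fused backward)
  for (i in 3:1) {
    lay <- cache$lay[[i]]
    C <- length(p$dec[[i]]$gamma)
    ggamma <- numeric(C); gbeta <- numeric(C)
    gms <- vector("list", B)
    for (b in seq_len(B)) {
      r <- bn_act_bw_cpp(g[[b]], lay$act[[b]], lay$xhat[[b]], 0.2, C)
      gms[[b]] <- r$gmasked
      gbeta <- gbeta + r$sum_g
      ggamma <- ggamma + r$sum_gx
    }
    grads$dec[[i]]$gamma <- ggamma
    grads$dec[[i]]$beta <- gbeta
    k <- p$dec[[i]]$gamma * lay$inv
    g_new <- vector("list", B)
    for (b in seq_len(B)) {
      gpre <- if (isTRUE(lay$train))
        bn_bw_train_cpp(gms[[b]], lay$xhat[[b]], k, gbeta / lay$n,
                        ggamma / lay$n)
      else channel_affine_cpp(gms[[b]], k, numeric(C))
      r <- conv3d_bw(lay$x[[b]], p$dec[[i]]$w, gpre)
      grads$dec[[i]]$w <- grads$dec[[i]]$w + r$gw
      g_new[[b]] <- r$gx
    }
    g <- g_new
  }
  # split decoder-input gradient into fused-map and edge-channel paths
  for (b in seq_len(B)) {
    gx0 <- g[[b]]
    gl <- matrix(rowSums(matrix(gx0[, , , 1L], E * E, E)), E, E)
    if (!ablate_sobel) {
      e <- cache$edges[[b]]
      ge <- array(gx0[, , , 2L], c(E, E, E, 1L))
      r <- conv3d_bw(array(e, c(E, E, E, 1L)), p$post$w, ge, need_gx = FALSE)
      grads$post$w <- grads$post$w + r$gw
      grads$post$b <- grads$post$b + r$gb
    }
    fb <- fuse_triple_bw(cache$fus[[b]]$cache, gl)
    for (vn in c("x", "y", "z")) {
      gv <- switch(vn, x = fb$gx, y = fb$gy, z = fb$gz)
      vg <- encode_view_bw(gv, p$enc[[vn]], cache$enc[[b]]$cache[[vn]],
                           cfg$enc)
      grads$enc[[vn]] <- tree_add(grads$enc[[vn]], vg)
    }
  }
  grads
}

#' Generate an MRI volume from a preprocessed PET volume
#'
#' Runs the generator in evaluation mode (BatchNorm uses running statistics;
#' output is deterministic).
#'
#' @param pet preprocessed PET volume (cubic, values in \[-1, 1\]).
#' @param gen generator state from [generator_init()] or [egan_train()].
#' @param cfg the [egan_config()] used to build `gen`.
#' @param ablate_sobel zero the geometric edge channel (ablation switch).
#' @param range_check `"warn"` (default), `"error"` or `"none"` when the
#'   input leaves \[-1, 1\] beyond `cfg$range_tol`.
#' @return Generated volume with values in (-1, 1).
#' @export
generator_forward <- function(pet, gen, cfg, ablate_sobel = FALSE,
                              range_check = c("warn", "error", "none")) {
  range_check <- match.arg(range_check)
  x <- vol_data(pet)
  if (range_check != "none" &&
      (min(x) < -1 - cfg$range_tol || max(x) > 1 + cfg$range_tol)) {
    msg <- sprintf("input range [%.3f, %.3f] is outside [-1, 1]; did you run preprocess_pet()?",
                   min(x), max(x))
    if (range_check == "error") stop(msg) else warning(msg)
  }
  edge <- if (ablate_sobel) NULL else apply_sobel(x)$data
  r <- generator_forward_batch(list(x), list(edge), gen, cfg,
                               train = FALSE, ablate_sobel = ablate_sobel)
  out <- as_volume(r$out[[1]],
                   spacing = if (inherits(pet, "volume")) pet$spacing else c(1, 1, 1),
                   affine = if (inherits(pet, "volume")) pet$affine else NULL)
  out
}

# Strided conv + LeakyReLU with a fused fast path (even extents, 4^3 kernel).
# LeakyReLU preserves sign, so its backward can read the sign off the
# activated output and no pre-activation needs caching.
conv_ds_fw <- function(x, w, b, slope = 0.2) {
  if (dim(w)[1] == 4L && all(dim(x)[1:3] %% 2L == 0L))
    conv4s2_fw_act_cpp(x, dim(x), w, b, slope)
  else
    lrelu_fw(conv3d_fw(x, w, b, stride = 2L, pad = 1L), slope)
}

conv_ds_bw <- function(x, w, gy, act, slope = 0.2, need_gx = TRUE) {
  if (dim(w)[1] == 4L && all(dim(x)[1:3] %% 2L == 0L))
    conv4s2_bw_act_cpp(x, dim(x), w, gy, act, slope, need_gx)
  else
    conv3d_bw(x, w, lrelu_bw(act, gy, slope), stride = 2L, pad = 1L,
              need_gx = need_gx)
}

disc_forward_one <- function(pet, cand, dp, cfg, cache = FALSE,
                             stacked = NULL) {
  E <- cfg$extent
  x <- if (is.null(stacked)) array(c(pet, cand), c(E, E, E, 2L)) else stacked
  hs <- list(x)
  for (i in seq_len(4L))
    hs[[i + 1]] <- conv_ds_fw(hs[[i]], dp[[i]]$w, dp[[i]]$b)
  f <- conv3d_fw(hs[[5]], dp$head$w, dp$head$b, stride = 1L, pad = 0L)
  m <- mean(f)
  prob <- sigmoid(m)
  if (!cache) return(prob)
  list(prob = prob, cache = list(hs = hs, f = f, prob = prob))
}

# dprob: dLoss/dprob. Returns grads (tree like dp) and gx (E^3 x 2 input grad).
disc_backward_one <- function(dprob, dp, cache, cfg, need_gx = FALSE) {
  grads <- tree_zero_like(dp)
  p <- cache$prob
  dm <- dprob * p * (1 - p)
  gf <- array(dm / length(cache$f), dim(cache$f))
  r <- conv3d_bw(cache$hs[[5]], dp$head$w, gf, stride = 1L, pad = 0L)
  grads$head$w <- r$gw; grads$head$b <- r$gb
  g <- r$gx
  for (i in 4:1) {
    r <- conv_ds_bw(cache$hs[[i]], dp[[i]]$w, g, cache$hs[[i + 1]],
                    need_gx = need_gx || i > 1L)
    grads[[i]]$w <- r$gw; grads[[i]]$b <- r$gb
    g <- r$gx
  }
  list(grads = grads, gx = if (need_gx) g else NULL)
}

#' Discriminator probability for a (PET, MRI) pair
#'
#' Conditional discriminator: the PET source and the candidate MRI are
#' stacked as two channels and mapped to a probability of being a real pair.
#'
#' @param pet,mri volumes or arrays on the same cubic grid.
#' @param disc discriminator state from [discriminator_init()]/[egan_train()].
#' @param cfg the matching [egan_config()].
#' @return Scalar probability strictly inside (0, 1).
#' @export
discriminate <- function(pet, mri, disc, cfg) {
  a <- vol_data(pet); b <- vol_data(mri)
  if (!identical(dim(a), dim(b)))
    stop("pet and mri shapes differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  if (!all(dim(a) == cfg$extent))
    stop("discriminator expects ", cfg$extent, "^3 volumes")
  disc_forward_one(a, b, disc$params, cfg)
}
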