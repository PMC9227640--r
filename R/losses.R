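# Hybrid objective: alpha1 * adversarial + alpha2 * L2, with the
# non-saturating generator form of the cGAN loss. At discriminator
# optimality the adversarial game minimizes the Jensen-Shannon divergence
# between the generated and real distributions; jsd() is exposed for
# monitoring over discretized intensity histograms.

#' Loss weights for the hybrid objective
#'
#' @param alpha1 adversarial weight (default 1).
#' @param alpha2 L2 weight (default 0.5).
#' @return List of class `loss_weights`.
#' @export
loss_weights <- function(alpha1 = 1, alpha2 = 0.5) {
  stopifnot(alpha1 >= 0, alpha2 >= 0, alpha1 + alpha2 > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2), class = "loss_weights")
}

#' Adversarial losses from discriminator probabilities
#'
#' Binary cross-entropy form of the cGAN min-max game. The discriminator
#' loss is `-[log d_real + log(1 - d_fake)]`; the generator uses the
#' non-saturating `-log d_fake`, which keeps gradients alive when the
#' discriminator wins early (the saturation problem). Probabilities are
#' clamped to `[eps, 1 - eps]` before the logs. Vector inputs are averaged
#' over the batch.
#'
#' @param d_real,d_fake discriminator probabilities in (0, 1).
#' @param eps log-clamp, default 1e-7.
#' @return List with `loss_d` and `loss_g`.
#' @export
adversarial_losses <- function(d_real, d_fake, eps = 1e-7) {
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  list(loss_d = -mean(log(dr) + log(1 - df)),
       loss_g = -mean(log(df)))
}

#' Mean squared voxelwise difference
#'
#' The L2 term is the mean (not the sum) over voxels so that the weight
#' `alpha2` is independent of volume resolution.
#'
#' @param gen,real volumes or arrays of identical shape.
#' @return Scalar mean squared error.
#' @export
l2_loss <- function(gen, real) {
  a <- vol_data(gen); b <- vol_data(real)
  if (!identical(dim(a), dim(b)))
    stop("l2_loss: shapes differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  mean((a - b)^2)
}

#' Jensen-Shannon divergence (nats)
#'
#' `JSD(p || q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`.
#' Symmetric, bounded in `[0, log 2]`, zero iff `p == q`.
#'
#' @param p,q non-negative probability vectors of equal length summing to 1
#'   (within 1e-9 by default).
#' @param tol tolerance on the sum-to-one check.
#' @return Scalar divergence in nats.
#' @export
jsd <- function(p, q, tol = 1e-9) {
  if (length(p) != length(q))
    stop("jsd: length mismatch (", length(p), " vs ", length(q), ")")
  if (any(p < 0) || any(q < 0)) stop("jsd: negative probability mass")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("jsd: inputs must sum to 1 (tol ", tol, ")")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Weighted hybrid objective
#'
#' @param loss_gan adversarial term.
#' @param loss_l2 L2 term.
#' @param w a [loss_weights()] object.
#' @return `alpha1 * loss_gan + alpha2 * loss_l2`.
#' @export
hybrid_loss <- function(loss_gan, loss_l2, w = loss_weights()) {
  w$alpha1 * loss_gan + w$alpha2 * loss_l2
}

#' Intensity histogram as a probability vector
#'
#' Discretizes a volume into equal-width bins over `range`, for JSD
#' monitoring between generated and real intensity distributions.
#'
#' @param v volume or array.
#' @param bins number of bins.
#' @param range intensity range; defaults to the volume's own range.
#' @return Probability vector of length `bins`.
#' @export
intensity_histogram <- function(v, bins = 64L, range = NULL) {
  x <- as.numeric(vol_data(v))
  if (is.null(range)) range <- base::range(x)
  br <- seq(range[1], range[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  h / sum(h)
}
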