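# Intrinsic evaluation: PSNR, SSIM, MAE, normalized cross-correlation;
# 3D grey-level co-occurrence matrices with Haralick texture features;
# three-class tissue analysis via intensity clustering.

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    stop(what, ": shapes differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB; `Inf` for identical inputs.
#'
#' @param a,b volumes or arrays of the same shape.
#' @param data_range dynamic range of the data (e.g. 2 for \[-1, 1\]).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = 1) {
  a <- vol_data(a); b <- vol_data(b)
  check_same_shape(a, b, "psnr")
  stopifnot(data_range > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Mean absolute error
#'
#' @inheritParams psnr
#' @return Mean of `|a - b|`.
#' @export
mae <- function(a, b) {
  a <- vol_data(a); b <- vol_data(b)
  check_same_shape(a, b, "mae")
  mean(abs(a - b))
}

#' Normalized cross-correlation
#'
#' Pearson correlation of the flattened voxel intensities (zero-mean
#' normalized), in \[-1, 1\].
#'
#' @inheritParams psnr
#' @return Scalar correlation.
#' @export
norm_xcorr <- function(a, b) {
  a <- as.numeric(vol_data(a)); b <- as.numeric(vol_data(b))
  if (length(a) != length(b)) stop("norm_xcorr: shapes differ")
  da <- a - mean(a); db <- b - mean(b)
  sa <- sqrt(sum(da^2)); sb <- sqrt(sum(db^2))
  if (sa == 0 || sb == 0)
    stop("norm_xcorr: zero-variance input")
  sum(da * db) / (sa * sb)
}

# Separable Gaussian filtering of a 3D array (reflected boundaries).
gaussian_filter3 <- function(x, sigma, radius = NULL) {
  if (sigma <= 0) return(x)
  if (is.null(radius)) radius <- max(1L, floor(3.5 * sigma + 0.5))
  for (a in 1:3) {
    n <- dim(x)[a]
    r <- min(radius, n - 1L)
    taps <- exp(-0.5 * ((-r:r) / sigma)^2)
    taps <- taps / sum(taps)
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + (-r:r)
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
      for (t in seq_along(idx)) M[i, idx[t]] <- M[i, idx[t]] + taps[t]
    }
    x <- apply_axis_op(x, a, M)
  }
  x
}

#' Structural similarity index (3D)
#'
#' Windowed SSIM with a 3D Gaussian window (sigma 1.5, 11^3 support for
#' volumes large enough), sample-covariance normalization, averaged over the
#' interior region unaffected by boundary padding.
#'
#' @inheritParams psnr
#' @param sigma Gaussian window standard deviation.
#' @return Mean SSIM in (-1, 1\]; 1 for identical inputs.
#' @export
ssim <- function(a, b, data_range = 1, sigma = 1.5) {
  a <- vol_data(a); b <- vol_data(b)
  check_same_shape(a, b, "ssim")
  stopifnot(data_range > 0)
  r <- max(1L, floor(3.5 * sigma + 0.5))
  r <- min(r, min(dim(a)) %/% 2 - 1L)
  if (r < 1L) stop("ssim: volume too small for the filter window")
  win <- 2L * r + 1L
  npts <- win^3
  cov_norm <- npts / (npts - 1)
  f <- function(x) gaussian_filter3(x, sigma, radius = r)
  ux <- f(a); uy <- f(b)
  uxx <- f(a * a); uyy <- f(b * b); uxy <- f(a * b)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  d <- dim(S)
  mean(S[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)])
}

#' Full similarity report for a generated/reference pair
#'
#' @inheritParams psnr
#' @return List of class `metrics_report` with `psnr`, `ssim`, `mae`,
#'   `xcorr`.
#' @export
evaluate_pair <- function(a, b, data_range = NULL) {
  a <- vol_data(a); b <- vol_data(b)
  if (is.null(data_range)) data_range <- max(max(a, b) - min(a, b), 1e-12)
  structure(list(psnr = psnr(a, b, data_range),
                 ssim = ssim(a, b, data_range),
                 mae = mae(a, b),
                 xcorr = norm_xcorr(a, b)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR %.3f dB | SSIM %.4f | MAE %.5f | XCorr %.4f\n",
              x$psnr, x$ssim, x$mae, x$xcorr))
  invisible(x)
}

# Discretize intensities into `levels` equal-width bins over [min, max].
quantize_levels <- function(x, levels) {
  mn <- min(x); mx <- max(x)
  if (mx <= mn) return(array(1L, dim(x)))
  q <- floor((x - mn) / (mx - mn) * levels) + 1L
  q[q > levels] <- levels
  array(as.integer(q), dim(x))
}

#' 3D grey-level co-occurrence matrix
#'
#' Discretizes the volume into `levels` equal-width grey bins and counts
#' co-occurring level pairs at the integer offset `round(distance *
#' direction)`, accumulated symmetrically (the counts matrix equals its
#' transpose). The published texture analysis uses 8 levels, distance 3 and
#' a 60-degree in-plane direction, i.e. offset (2, 3, 0).
#'
#' @param v volume or array.
#' @param levels number of grey levels (>= 2).
#' @param distance offset length in voxels.
#' @param direction length-3 direction vector (need not be normalized to a
#'   lattice vector; it is scaled by `distance` and rounded).
#' @return Object of class `glcm`: `levels`, `offset`, `counts`,
#'   `normalized` (sums to 1).
#' @export
glcm_3d <- function(v, levels = 8L, distance = 3L,
                    direction = c(cos(pi / 3), sin(pi / 3), 0)) {
  # accepts arbitrarily small 3D arrays (a 2x2x2 block is a valid input)
  x <- if (is.array(v) && length(dim(v)) == 3L) v else vol_data(v)
  stopifnot(levels >= 2L)
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("glcm_3d: direction must be non-zero")
  off <- as.integer(round(distance * direction / nrm))
  if (all(off == 0L))
    stop("glcm_3d: offset rounds to (0,0,0); increase distance")
  d <- dim(x)
  if (any(d <= abs(off)))
    stop("glcm_3d: volume extent ", paste(d, collapse = "x"),
         " too small for offset (", paste(off, collapse = ","), ")")
  q <- quantize_levels(x, levels)
  src <- lapply(1:3, function(a) {
    o <- off[a]
    if (o >= 0) seq_len(d[a] - o) else seq.int(1L - o, d[a])
  })
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  qa <- q[src[[1]], src[[2]], src[[3]], drop = FALSE]
  qb <- q[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  counts <- matrix(0, levels, levels)
  tab <- tabulate((qa - 1L) * levels + qb, nbins = levels * levels)
  counts[] <- tab
  counts <- t(counts)          # row = level at source voxel
  counts <- counts + t(counts) # symmetric accumulation
  structure(list(levels = levels, offset = off, counts = counts,
                 normalized = counts / sum(counts)),
            class = "glcm")
}

#' Haralick texture features of a GLCM
#'
#' `energy = sum p^2`, `contrast = sum (i-j)^2 p`, `dissimilarity =
#' sum |i-j| p`, `homogeneity = sum p / (1 + (i-j)^2)`, over the normalized
#' co-occurrence matrix.
#'
#' @param m a [glcm_3d()] object, or an L x L normalized matrix.
#' @return List of class `haralick_features`.
#' @export
haralick <- function(m) {
  p <- if (inherits(m, "glcm")) m$normalized else m
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop("haralick: need a square co-occurrence matrix")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("haralick: matrix must be normalized (non-negative, sum 1)")
  L <- nrow(p)
  i <- row(p); j <- col(p)
  structure(list(
    energy = sum(p^2),
    homogeneity = sum(p / (1 + (i - j)^2)),
    dissimilarity = sum(abs(i - j) * p),
    contrast = sum((i - j)^2 * p)),
    class = "haralick_features")
}

# The 13 unique 3D direction classes (up to sign) on the unit lattice.
glcm_directions_13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(-1, 1, 1))
}

#' Haralick features averaged over the 13 3D directions
#'
#' Cohort-style texture summary: computes the GLCM at `distance` along each
#' of the 13 unique 3D lattice directions and averages the four Haralick
#' features.
#'
#' @inheritParams glcm_3d
#' @return `haralick_features` list of direction-averaged values.
#' @export
haralick_summary <- function(v, levels = 8L, distance = 3L) {
  dirs <- glcm_directions_13()
  acc <- c(energy = 0, homogeneity = 0, dissimilarity = 0, contrast = 0)
  for (k in seq_len(nrow(dirs))) {
    h <- haralick(glcm_3d(v, levels, distance, dirs[k, ]))
    acc <- acc + unlist(h) / nrow(dirs)
  }
  structure(as.list(acc), class = "haralick_features")
}

#' Three-class tissue segmentation by intensity clustering
#'
#' K-means (k = 3) on voxel intensities with deterministic quantile
#' initialization; labels are ordered by ascending class mean so that
#' 0 = CSF-like (darkest), 1 = GM-like, 2 = WM-like (brightest) on a
#' T1-weighted contrast. A lightweight intensity-only segmenter for tissue
#' analysis, not an anatomical segmentation.
#'
#' @param v volume or array with at least 3 distinct intensity modes.
#' @param mask optional logical array restricting the clustering (voxels
#'   outside keep label `NA`).
#' @return Integer array of labels in \{0, 1, 2\} (NA outside the mask).
#' @export
segment_three_class <- function(v, mask = NULL) {
  x <- vol_data(v)
  sel <- if (is.null(mask)) rep(TRUE, length(x)) else as.logical(mask)
  vals <- as.numeric(x[sel])
  if (length(unique(vals)) < 3L)
    stop("segment_three_class: fewer than 3 distinct intensities")
  centers <- matrix(quantile(vals, c(0.1, 0.5, 0.9), names = FALSE), ncol = 1)
  if (any(duplicated(centers)))
    centers <- matrix(quantile(unique(vals), c(0.1, 0.5, 0.9),
                               names = FALSE), ncol = 1)
  km <- kmeans(matrix(vals, ncol = 1), centers = centers,
               iter.max = 100L, algorithm = "Lloyd")
  ord <- order(km$centers)
  relabel <- integer(3L); relabel[ord] <- 0:2
  lab <- array(NA_integer_, dim(x))
  lab[sel] <- relabel[km$cluster]
  lab
}

#' Per-tissue mean intensity comparison
#'
#' For each tissue class, the mean voxel value of the generated and the
#' reference volume over the class mask (the per-tissue average-value
#' analysis of the evaluation suite).
#'
#' @param gen,real volumes or arrays of identical shape.
#' @param labels integer label array from [segment_three_class()] (or a
#'   ground-truth tissue map); NA voxels are ignored.
#' @return Data frame with `class`, `n_voxels`, `mean_gen`, `mean_real`,
#'   `diff`. Empty classes are flagged with `n_voxels = 0`.
#' @export
tissue_mean_report <- function(gen, real, labels) {
  a <- vol_data(gen); b <- vol_data(real)
  check_same_shape(a, b, "tissue_mean_report")
  if (!identical(dim(labels), dim(a)))
    stop("tissue_mean_report: label shape mismatch")
  cls <- sort(unique(labels[!is.na(labels)]))
  rows <- lapply(cls, function(k) {
    m <- !is.na(labels) & labels == k
    n <- sum(m)
    data.frame(class = k, n_voxels = n,
               mean_gen = if (n > 0) mean(a[m]) else NA_real_,
               mean_real = if (n > 0) mean(b[m]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$diff <- out$mean_gen - out$mean_real
  out
}
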