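# Preprocessing chain: PET global-mean intensity normalization, anti-aliased
# down-sizing to a common cubic grid, and voxel normalization to [-1, 1].
# Spatial registration happens upstream; inputs are assumed co-registered.

#' Normalize PET intensities by the global average
#'
#' Divides every voxel by the volume's global mean so the returned volume has
#' mean 1. Idempotent.
#'
#' @param v volume or 3D array.
#' @return Volume with global mean 1.
#' @export
intensity_normalize_pet <- function(v) {
  v <- as_volume(v)
  m <- mean(v$data)
  if (!is.finite(m) || m <= 0)
    stop("global mean must be strictly positive for PET intensity normalization, got ", m)
  v$data <- v$data / m
  v
}

#' Rescale voxel intensities to a target range
#'
#' Affine intensity mapping sending the volume minimum to `lo` and maximum to
#' `hi` (defaults: \[-1, 1\], the network's working range).
#'
#' @param v volume or 3D array.
#' @param lo,hi target range bounds, `lo < hi`.
#' @return Rescaled volume; min equals `lo`, max equals `hi`.
#' @export
rescale_to_range <- function(v, lo = -1, hi = 1) {
  v <- as_volume(v)
  stopifnot(lo < hi)
  mn <- min(v$data); mx <- max(v$data)
  if (mx <= mn)
    stop("cannot rescale a constant volume (min == max == ", mn, ")")
  v$data <- (v$data - mn) / (mx - mn) * (hi - lo) + lo
  v
}

# Row-stochastic 1D resampling operator (n_out x n_in): Gaussian anti-alias
# prefilter (sigma = (factor-1)/2 for downscale factor > 1, reflected
# boundaries) composed with linear interpolation at pixel centers.
resample_operator <- function(n_in, n_out) {
  factor <- n_in / n_out
  sigma <- max(0, (factor - 1) / 2)
  G <- diag(n_in)
  if (sigma > 1e-12) {
    r <- max(1L, ceiling(3 * sigma))
    taps <- exp(-0.5 * ((-r:r) / sigma)^2)
    taps <- taps / sum(taps)
    G <- matrix(0, n_in, n_in)
    for (i in seq_len(n_in)) {
      idx <- i + (-r:r)
      idx <- ifelse(idx < 1L, 1L - idx + 0L, idx)       # reflect low edge
      idx <- ifelse(idx > n_in, 2L * n_in + 1L - idx, idx)  # reflect high edge
      for (t in seq_along(idx)) G[i, idx[t]] <- G[i, idx[t]] + taps[t]
    }
  }
  # pixel-center aligned linear interpolation
  L <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    xc <- (i - 0.5) * factor + 0.5
    xc <- min(max(xc, 1), n_in)
    j0 <- floor(xc); j1 <- min(j0 + 1, n_in)
    wt <- xc - j0
    L[i, j0] <- L[i, j0] + (1 - wt)
    L[i, j1] <- L[i, j1] + wt
  }
  L %*% G
}

# Apply matrix M (n_out x n_in) along one axis of a 3D array.
apply_axis_op <- function(arr, axis, M) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  x <- M %*% matrix(x, d[axis], prod(d[-axis]))
  dim(x) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(x, order(perm))
}

#' Anti-aliased resize of a volume
#'
#' Separable per-axis resampling: a Gaussian prefilter with sigma proportional
#' to the downscale factor, followed by linear interpolation at pixel centers.
#' Constant volumes are preserved exactly. Upsizing is refused unless
#' explicitly allowed, since the pipeline is a down-sizing one.
#'
#' @param v volume or 3D array.
#' @param target_shape integer triple, each entry at least 3.
#' @param allow_upsize permit target dimensions larger than the input.
#' @return Resized volume; spacing is scaled by the per-axis factors.
#' @export
resize_antialias <- function(v, target_shape = c(90L, 90L, 90L),
                             allow_upsize = FALSE) {
  v <- as_volume(v)
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 3L))
  d <- dim(v$data)
  if (!allow_upsize && any(target_shape > d))
    stop("target shape ", paste(target_shape, collapse = "x"),
         " would upsize input ", paste(d, collapse = "x"),
         "; set allow_upsize = TRUE to permit")
  out <- v$data
  for (a in 1:3) {
    if (target_shape[a] != d[a])
      out <- apply_axis_op(out, a, resample_operator(d[a], target_shape[a]))
  }
  factors <- d / target_shape
  aff <- v$affine
  aff[, 1:3] <- aff[, 1:3] %*% diag(factors)
  as_volume(out, spacing = v$spacing * factors, affine = aff)
}

#' Full PET preprocessing chain
#'
#' Global-mean intensity normalization, anti-aliased resize to
#' `target_shape`, then rescale to \[-1, 1\].
#'
#' @param v PET volume.
#' @param target_shape common grid, default 90^3.
#' @return Preprocessed volume in \[-1, 1\].
#' @export
preprocess_pet <- function(v, target_shape = c(90L, 90L, 90L)) {
  rescale_to_range(resize_antialias(intensity_normalize_pet(v), target_shape))
}

#' MRI preprocessing chain
#'
#' Anti-aliased resize then rescale to \[-1, 1\]. MRI intensities carry no
#' tracer-dose scale, so no global-mean normalization is applied.
#'
#' @inheritParams preprocess_pet
#' @return Preprocessed volume in \[-1, 1\].
#' @export
preprocess_mri <- function(v, target_shape = c(90L, 90L, 90L)) {
  rescale_to_range(resize_antialias(as_volume(v), target_shape))
}
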