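# Independent brute-force oracles, written as plain scalar loops so they
# share no code path with the implementation they check.

# reflected (half-sample symmetric) index
reflect_idx <- function(i, n) {
  if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i
}

# full 3x3x3 cross-correlation with one Sobel axis kernel, triple loop
bf_sobel_response <- function(v, k) {
  d <- dim(v)
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      acc <- acc + k[dx + 2, dy + 2, dz + 2] *
        v[reflect_idx(x + dx, d[1]), reflect_idx(y + dy, d[2]),
          reflect_idx(z + dz, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

bf_sobel_magnitude <- function(v) {
  gx <- bf_sobel_response(v, sobel_kernel("x")$weights)
  gy <- bf_sobel_response(v, sobel_kernel("y")$weights)
  gz <- bf_sobel_response(v, sobel_kernel("z")$weights)
  sqrt(gx^2 + gy^2 + gz^2)
}

# scalar-loop similarity metrics
bf_psnr <- function(a, b, data_range) {
  s <- 0; n <- 0
  for (i in seq_along(a)) { s <- s + (a[i] - b[i])^2; n <- n + 1 }
  10 * log10(data_range^2 / (s / n))
}
bf_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}
bf_xcorr <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# exhaustive symmetric co-occurrence enumeration
bf_glcm_counts <- function(v, levels, off) {
  d <- dim(v)
  mn <- min(v); mx <- max(v)
  q <- if (mx > mn) pmin(floor((v - mn) / (mx - mn) * levels) + 1, levels)
       else array(1, d)
  counts <- matrix(0, levels, levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 >= 1 && x2 <= d[1] && y2 >= 1 && y2 <= d[2] &&
        z2 >= 1 && z2 <= d[3]) {
      i <- q[x, y, z]; j <- q[x2, y2, z2]
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts
}

# scalar tanh-normalized Hadamard fusion (the printed column-sum reading)
bf_fuse_pair <- function(x, y, eps = 1e-8) {
  n <- nrow(x)
  g <- matrix(0, n, n)
  for (j in seq_len(n)) {
    tcol <- numeric(n)
    for (i in seq_len(n)) tcol[i] <- tanh(x[i, j] * y[j, i])
    s <- sum(tcol)
    s <- s + eps * (if (s >= 0) 1 else -1)
    for (i in seq_len(n)) g[i, j] <- tcol[i] / s
  }
  g
}

# double-loop Haralick sums
bf_haralick <- function(p) {
  L <- nrow(p)
  en <- 0; hom <- 0; dis <- 0; con <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    en <- en + p[i, j]^2
    hom <- hom + p[i, j] / (1 + (i - j)^2)
    dis <- dis + abs(i - j) * p[i, j]
    con <- con + (i - j)^2 * p[i, j]
  }
  list(energy = en, homogeneity = hom, dissimilarity = dis, contrast = con)
}

# tiny training fixtures
tiny_cfg <- function(extent = 16L, epochs = 2L, ...) {
  egan_config("desk", extent = extent, epochs = epochs, batch_size = 2L,
              dec_channels = c(3L, 3L, 3L), disc_channels = c(4L, 4L, 4L, 4L),
              checkpoint_every = 1L, ...)
}

tiny_dataset <- function(n = 4L, extent = 16L, seed = 11L) {
  ds <- make_dataset(n, phantom_spec(extent = extent, seed = seed))
  preprocess_dataset(ds$pairs, extent)
}
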