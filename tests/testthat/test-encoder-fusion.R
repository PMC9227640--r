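cfg8 <- encoder_config(8L, channels_a = 2L, channels_b = 2L, channels_2d = 3L)

test_that("encoder maps a cubic volume to three square view maps", {
  set.seed(31)
  params <- init_weights(egan3d:::encoder_init(cfg8), 0.05)
  v <- array(rnorm(8^3), c(8, 8, 8))
  fm <- encode_views(v, params, cfg8)
  expect_identical(dim(fm$x), c(8L, 8L))
  expect_identical(dim(fm$y), c(8L, 8L))
  expect_identical(dim(fm$z), c(8L, 8L))
  expect_true(all(is.finite(c(fm$x, fm$y, fm$z))))

  # determinism under fixed parameters
  fm2 <- encode_views(v, params, cfg8)
  expect_identical(fm$x, fm2$x)
  expect_identical(fm$z, fm2$z)

  # all-zero parameters collapse to all-zero maps (linearity)
  zero <- egan3d:::tree_map(function(x) x * 0, params)
  fz <- encode_views(v, zero, cfg8)
  expect_equal(fz$x, matrix(0, 8, 8))
  expect_equal(fz$y, matrix(0, 8, 8))

  expect_error(encode_views(array(0, c(8, 8, 9)), params, cfg8), "8")
})

test_that("pairwise fusion follows the tanh-normalized Hadamard rule", {
  # identical constant positive maps: every entry 1/N
  a <- matrix(0.7, 5, 5)
  expect_equal(fuse_pair(a, a), matrix(1 / 5, 5, 5), tolerance = 1e-7)

  # column sums are 1 on strictly positive maps
  set.seed(32)
  x <- matrix(runif(36, 0.1, 2), 6); y <- matrix(runif(36, 0.1, 2), 6)
  expect_equal(colSums(fuse_pair(x, y)), rep(1, 6), tolerance = 1e-6)

  # the 2x2 case against the scalar oracle
  x2 <- matrix(c(1, 3, 2, 4), 2)  # [[1,2],[3,4]] row-wise
  y2 <- diag(2)
  expect_equal(fuse_pair(x2, y2), bf_fuse_pair(x2, y2), tolerance = 1e-12)

  expect_error(fuse_pair(matrix(1, 2, 2), matrix(1, 3, 3)), "square")
})

test_that("triple fusion chains the rule and stays finite in degenerate cases", {
  set.seed(33)
  x <- matrix(runif(9, 0.2, 1), 3); y <- matrix(runif(9, 0.2, 1), 3)
  z <- matrix(runif(9, 0.2, 1), 3)
  f <- fuse_triple(x, y, z)
  expect_equal(f$g, fuse_pair(x, y), tolerance = 1e-14)
  expect_equal(f$l, fuse_pair(f$g, z), tolerance = 1e-14)

  # all-equal positive constants: l is uniform 1/N
  cm <- matrix(1.3, 4, 4)
  expect_equal(fuse_triple(cm, cm, cm)$l, matrix(0.25, 4, 4),
               tolerance = 1e-6)

  # zero third view makes every second-stage tanh argument 0: eps guard
  fz <- fuse_triple(x, y, matrix(0, 3, 3))
  expect_true(all(is.finite(fz$l)))

  # tanh fusion is NOT scale invariant (it is not a softmax)
  f2 <- fuse_triple(2 * x, 2 * y, 2 * z)
  expect_gt(max(abs(f2$l - f$l)), 1e-6)
})

test_that("fusion is consistent under simultaneous row/column relabeling", {
  set.seed(34)
  x <- matrix(runif(9, 0.1, 1), 3); y <- matrix(runif(9, 0.1, 1), 3)
  z <- matrix(runif(9, 0.1, 1), 3)
  p <- c(2, 3, 1)
  # permuting both indices of all inputs permutes l identically
  l1 <- fuse_triple(x, y, z)$l[p, p]
  l2 <- fuse_triple(x[p, p], y[p, p], z[p, p])$l
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("gradient flows into all three encoder view branches", {
  cfg <- tiny_cfg(extent = 8L)
  set.seed(35)
  gen <- generator_init(cfg)
  pets <- list(array(tanh(rnorm(8^3)), c(8, 8, 8)))
  edges <- lapply(pets, function(p) apply_sobel(p)$data)
  fw <- egan3d:::generator_forward_batch(pets, edges, gen, cfg, train = TRUE)
  gouts <- lapply(fw$out, function(o) o * 0 + 1 / length(o))
  gr <- egan3d:::generator_backward_batch(gouts, gen, fw$cache, cfg)
  for (vn in c("x", "y", "z")) {
    total <- sum(abs(unlist(gr$enc[[vn]])))
    expect_gt(total, 0)
  }
})
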