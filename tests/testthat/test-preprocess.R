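test_that("PET global-mean normalization has unit mean and is idempotent", {
  const <- as_volume(array(7, c(4, 4, 4)))
  expect_equal(intensity_normalize_pet(const)$data, array(1, c(4, 4, 4)))

  set.seed(3)
  v <- as_volume(array(runif(6^3, 0.1, 5), c(6, 6, 6)))
  n1 <- intensity_normalize_pet(v)
  expect_equal(mean(n1$data), 1, tolerance = 1e-12)
  n2 <- intensity_normalize_pet(n1)
  expect_equal(n2$data, n1$data, tolerance = 1e-6)

  # hand-division oracle on a grid holding 1..8 repeated (mean 4.5)
  g <- as_volume(array(rep(1:8, each = 8), c(4, 4, 4)))
  ng <- intensity_normalize_pet(g)
  expect_equal(max(ng$data), 8 / 4.5, tolerance = 1e-12)
  expect_equal(sort(unique(as.numeric(ng$data))), (1:8) / 4.5,
               tolerance = 1e-12)

  expect_error(intensity_normalize_pet(as_volume(array(0, c(3, 3, 3)) + 0)),
               "positive")
})

test_that("range rescaling is an exact affine map onto [lo, hi]", {
  v <- as_volume(array(seq(0, 10, length.out = 27), c(3, 3, 3)))
  r <- rescale_to_range(v)
  expect_equal(min(r$data), -1)
  expect_equal(max(r$data), 1)
  expect_equal(r$data[which(v$data == 5)], 0, tolerance = 1e-12)

  lin <- as_volume(array(rep(c(2, 4, 6), length.out = 27), c(3, 3, 3)))
  rl <- rescale_to_range(lin)
  expect_setequal(unique(as.numeric(rl$data)), c(-1, 0, 1))

  set.seed(4)
  x <- array(rnorm(5^3), c(5, 5, 5))
  rx <- rescale_to_range(as_volume(x))$data
  expect_identical(order(x), order(rx))  # monotone

  expect_error(rescale_to_range(as_volume(array(3, c(3, 3, 3)))), "constant")
})

test_that("anti-aliased resize preserves constants, identity and low-frequency content", {
  const <- as_volume(array(0.5, c(24, 24, 24)))
  r <- resize_antialias(const, c(9, 9, 9))
  expect_equal(r$data, array(0.5, c(9, 9, 9)), tolerance = 1e-12)
  expect_equal(r$spacing, c(24, 24, 24) / 9)

  v <- as_volume(array(rnorm(10^3), c(10, 10, 10)))
  expect_equal(resize_antialias(v, c(10, 10, 10))$data, v$data)

  g <- seq(0, 2 * pi, length.out = 40)
  sino <- as_volume(outer(sin(g), outer(cos(g), rep(1, 40))) + 2)
  rs <- resize_antialias(sino, c(13, 13, 13))
  expect_lt(abs(mean(rs$data) - mean(sino$data)) / mean(sino$data), 0.01)

  expect_error(resize_antialias(v, c(20, 10, 10)), "upsize")
  expect_silent(resize_antialias(v, c(20, 10, 10), allow_upsize = TRUE))
})

test_that("modality preprocessing chains land in [-1, 1] at the target grid", {
  set.seed(5)
  pet <- as_volume(array(runif(20^3, 0, 50), c(20, 20, 20)))
  mri <- as_volume(array(runif(20^3, 0, 900), c(20, 20, 20)))
  p <- preprocess_pet(pet, c(12, 12, 12))
  m <- preprocess_mri(mri, c(12, 12, 12))
  for (v in list(p, m)) {
    expect_identical(dim(v$data), c(12L, 12L, 12L))
    expect_equal(range(v$data), c(-1, 1))
  }
})
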