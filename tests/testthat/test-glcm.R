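test_that("co-occurrence counts match exhaustive pair enumeration", {
  v8 <- array(0:7, c(2, 2, 2))
  g <- glcm_3d(v8, levels = 8, distance = 1, direction = c(1, 0, 0))
  expect_identical(g$offset, c(1L, 0L, 0L))
  expect_equal(g$counts, bf_glcm_counts(v8, 8, c(1, 0, 0)))
  expect_equal(sum(g$normalized), 1, tolerance = 1e-12)

  set.seed(61)
  for (off in list(c(1, 0, 0), c(0, 2, 0), c(1, 1, 1))) {
    v <- array(runif(4^3), c(4, 4, 4))
    g <- glcm_3d(v, levels = 8, distance = sqrt(sum(off^2)),
                 direction = off / sqrt(sum(off^2)))
    expect_identical(g$offset, as.integer(off))
    expect_equal(g$counts, bf_glcm_counts(v, 8, off))
    expect_equal(g$counts, t(g$counts))              # symmetric accumulation
    expect_true(all(g$counts == round(g$counts)))    # integral counts
    expect_equal(sum(g$normalized), 1, tolerance = 1e-12)
  }
})

test_that("constant volumes concentrate all co-occurrence in one cell", {
  g <- glcm_3d(array(2.5, c(4, 4, 4)), levels = 8, distance = 1,
               direction = c(1, 0, 0))
  expect_equal(sum(g$normalized), 1, tolerance = 1e-12)
  expect_equal(max(diag(g$normalized)), 1, tolerance = 1e-12)
})

test_that("the published direction convention rounds to offset (2, 3, 0)", {
  set.seed(62)
  v <- array(runif(8^3), c(8, 8, 8))
  g <- glcm_3d(v)  # defaults: 8 levels, distance 3, 60-degree in-plane
  expect_identical(g$offset, c(2L, 3L, 0L))
  expect_error(glcm_3d(v, direction = c(0, 0, 0)), "non-zero")
  expect_error(glcm_3d(array(1, c(3, 3, 3)), distance = 3,
                       direction = c(1, 0, 0)), "too small")
})

test_that("Haralick features: degenerate cases and the double-loop oracle", {
  # diagonal-only GLCM: no grey-level contrast at all
  d <- diag(8) / 8
  h <- haralick(d)
  expect_equal(h$contrast, 0)
  expect_equal(h$dissimilarity, 0)
  expect_equal(h$homogeneity, 1)

  # uniform GLCM: energy is exactly 1/L^2
  u <- matrix(1 / 64, 8, 8)
  expect_identical(haralick(u)$energy, 1 / 64)
  expect_equal(haralick(u)$energy, 0.015625)

  set.seed(63)
  p <- matrix(runif(16), 4); p <- p / sum(p)
  h <- haralick(p)
  o <- bf_haralick(p)
  for (f in names(o)) expect_equal(h[[f]], o[[f]], tolerance = 1e-12)
  expect_true(h$energy > 0 && h$energy <= 1)
  expect_lte(h$homogeneity, 1)

  expect_error(haralick(matrix(1, 4, 4)), "normalized")
})

test_that("direction-averaged Haralick summary is finite and in range", {
  set.seed(64)
  v <- array(runif(10^3), c(10, 10, 10))
  h <- haralick_summary(v, levels = 8, distance = 2)
  expect_true(all(vapply(h, is.finite, logical(1))))
  expect_true(h$energy > 0 && h$energy <= 1 && h$homogeneity <= 1)
  expect_true(h$contrast >= 0 && h$dissimilarity >= 0)
})
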