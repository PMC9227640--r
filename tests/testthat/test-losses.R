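test_that("adversarial losses match their closed forms", {
  u <- adversarial_losses(0.5, 0.5)
  expect_equal(u$loss_d, 2 * log(2), tolerance = 1e-12)
  expect_equal(u$loss_g, log(2), tolerance = 1e-12)

  h <- adversarial_losses(0.8, 0.3)
  expect_equal(h$loss_d, -(log(0.8) + log(0.7)), tolerance = 1e-12)
  expect_equal(h$loss_d, 0.5798185, tolerance = 1e-6)

  # perfect-discriminator limit; clamp keeps the logs finite at 0/1
  p <- adversarial_losses(1, 0)
  expect_lt(p$loss_d, 1e-6)
  expect_true(is.finite(p$loss_g))

  # batches average
  b <- adversarial_losses(c(0.5, 0.8), c(0.5, 0.3))
  expect_equal(b$loss_d, (2 * log(2) - log(0.8) - log(0.7)) / 2,
               tolerance = 1e-12)
})

test_that("L2 loss is the voxelwise mean square", {
  a <- array(rnorm(4^3), c(4, 4, 4))
  expect_identical(l2_loss(a, a), 0)
  expect_equal(l2_loss(a, a + 0.1), 0.01, tolerance = 1e-12)
  set.seed(41)
  b <- array(rnorm(4^3), c(4, 4, 4))
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  expect_equal(l2_loss(a, b), s / 64, tolerance = 1e-12)
  expect_error(l2_loss(a, array(0, c(4, 4, 5))), "differ")
})

test_that("Jensen-Shannon divergence: identity, symmetry, bounds, closed forms", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(6); p <- p / sum(p)
    q <- runif(6); q <- q / sum(q)
    expect_equal(jsd(p, p), 0, tolerance = 1e-14)
    expect_equal(jsd(p, q), jsd(q, p), tolerance = 1e-12)
    expect_gte(jsd(p, q), 0)
    expect_lte(jsd(p, q), log(2) + 1e-12)
  }
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  hand <- 0.5 * log(4 / 3) + 0.5 * (0.5 * log(2 / 3) + 0.5 * log(2))
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), hand, tolerance = 1e-10)
  expect_equal(hand, 0.2157616, tolerance = 1e-6)
  expect_error(jsd(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(jsd(c(1.2, -0.2), c(0.5, 0.5)), "negative")
  expect_error(jsd(c(0.7, 0.7), c(0.5, 0.5)), "sum")
})

test_that("weighted hybrid objective combines the two terms linearly", {
  expect_equal(hybrid_loss(1, 0), 1)
  expect_equal(hybrid_loss(0, 2), 1)          # alpha2 = 0.5 default
  expect_equal(hybrid_loss(0.6, 0.4), 0.8)
  w <- loss_weights(2, 1)
  expect_equal(hybrid_loss(0.5, 0.25, w), 1.25)
  expect_error(loss_weights(0, 0))
  expect_error(loss_weights(-1, 1))
})

test_that("at the optimal discriminator the adversarial value equals 2 JSD - 2 log 2", {
  # two-point toy distributions; D*(x) = pr(x) / (pr(x) + pg(x))
  set.seed(43)
  for (i in 1:10) {
    pr <- runif(2); pr <- pr / sum(pr)
    pg <- runif(2); pg <- pg / sum(pg)
    dstar <- pr / (pr + pg)
    value <- sum(pr * log(dstar)) + sum(pg * log(1 - dstar))
    expect_equal(value, 2 * jsd(pg, pr) - 2 * log(2), tolerance = 1e-10)
  }
})

test_that("intensity histograms are valid probability vectors", {
  set.seed(44)
  v <- array(rnorm(8^3), c(8, 8, 8))
  h <- intensity_histogram(v, bins = 32)
  expect_length(h, 32L)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_true(all(h >= 0))
  expect_equal(jsd(h, h), 0)
})
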