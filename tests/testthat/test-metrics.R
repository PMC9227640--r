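test_that("PSNR: sentinel, closed forms and the 6 dB halving law", {
  a <- array(runif(3^3), c(3, 3, 3))
  expect_identical(psnr(a, a, 1), Inf)
  expect_equal(psnr(a, a + 0.5, 1), 10 * log10(1 / 0.25), tolerance = 1e-12)
  expect_equal(psnr(a, a + 0.5, 1), 6.0206, tolerance = 1e-4)
  expect_equal(psnr(a, a + 0.25, 1) - psnr(a, a + 0.5, 1),
               20 * log10(2), tolerance = 1e-10)
  expect_error(psnr(a, array(0, c(3, 3, 4)), 1), "differ")
})

test_that("PSNR, MAE and XCorr match scalar brute-force loops", {
  set.seed(51)
  for (i in 1:3) {
    a <- array(rnorm(3^3), c(3, 3, 3))
    b <- array(rnorm(3^3), c(3, 3, 3))
    expect_equal(psnr(a, b, 2), bf_psnr(a, b, 2), tolerance = 1e-10)
    expect_equal(mae(a, b), bf_mae(a, b), tolerance = 1e-10)
    expect_equal(norm_xcorr(a, b), bf_xcorr(a, b), tolerance = 1e-10)
  }
  expect_identical(mae(a, a), 0)
  expect_equal(mae(a, a + 3), 3, tolerance = 1e-12)
  expect_equal(norm_xcorr(a, a), 1, tolerance = 1e-12)
  az <- a - mean(a)
  expect_equal(norm_xcorr(az, -az), -1, tolerance = 1e-12)
  expect_error(norm_xcorr(a, array(1, c(3, 3, 3))), "variance")
})

test_that("SSIM equals 1 on identity and matches an independent reference implementation", {
  n <- 24
  x <- 1:n
  A <- (array(rep(sin(x / 2), n * n), c(n, n, n)) +
        array(rep(rep(cos(x / 3), each = n), n), c(n, n, n)) +
        array(rep(sin(x / 5), each = n * n), c(n, n, n)) + 3) / 6
  expect_equal(ssim(A, A, 1), 1, tolerance = 1e-12)

  # frozen values from scikit-image structural_similarity on these exact
  # analytic volumes (gaussian_weights=TRUE, sigma=1.5, sample covariance)
  B <- pmin(pmax(0.8 * A + 0.1 +
                   0.05 * sin(array(rep(outer(x, x), n), c(n, n, n)) / 7),
                 0), 1)
  expect_equal(ssim(A, B, 1), 0.9041405128, tolerance = 1e-7)
  expect_equal(ssim(A, 1 - A, 1), -0.7483101468, tolerance = 1e-7)
  expect_lt(ssim(A, 1 - A, 1), 0.5)  # contrast inversion is penalized
  Az <- A - mean(A)
  expect_equal(ssim(Az, 1.7 * Az, 1), 0.7706132885, tolerance = 1e-7)
  expect_lt(ssim(Az, 1.7 * Az, 1), 1)
})

test_that("PSNR and SSIM decrease monotonically with added noise", {
  set.seed(52)
  base <- array(runif(16^3), c(16, 16, 16))
  noise <- array(rnorm(16^3), c(16, 16, 16))
  sigmas <- c(0.01, 0.03, 0.08, 0.2, 0.5)
  ps <- vapply(sigmas, function(s) psnr(base, base + s * noise, 1), numeric(1))
  ss <- vapply(sigmas, function(s) ssim(base, base + s * noise, 1), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(diff(ss) < 0))
})

test_that("evaluate_pair aggregates the four similarity metrics", {
  set.seed(53)
  a <- array(runif(10^3), c(10, 10, 10))
  r <- evaluate_pair(a, a + 0.05, data_range = 1)
  expect_s3_class(r, "metrics_report")
  expect_equal(r$mae, 0.05, tolerance = 1e-12)
  expect_true(r$psnr > 20 && r$ssim <= 1 && abs(r$xcorr) <= 1)
})
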