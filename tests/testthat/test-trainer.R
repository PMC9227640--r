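test_that("weight initialization is reproducible with the right moments", {
  cfg <- tiny_cfg()
  set.seed(91); a <- generator_init(cfg)
  set.seed(91); b <- generator_init(cfg)
  expect_identical(a$params, b$params)

  big <- list(w = array(0, c(50, 40, 50)))  # 1e5 weights
  set.seed(92)
  big <- init_weights(big, 0.02)
  expect_lt(abs(sd(big$w) - 0.02) / 0.02, 0.05)
  expect_lt(abs(mean(big$w)), 3 * 0.02 / sqrt(length(big$w)))

  # biases zeroed, BatchNorm affine reset
  expect_equal(a$params$dec$l4$b, numeric(1))
  expect_equal(a$params$dec$l1$gamma, rep(1, cfg$dec_channels[1]))
  expect_equal(a$params$dec$l1$beta, numeric(cfg$dec_channels[1]))
})

test_that("a short training run completes with finite, logged losses", {
  pairs <- tiny_dataset(n = 4L, extent = 16L)
  cfg <- tiny_cfg(extent = 16L, epochs = 2L, seed = 5L)
  fit <- egan_train(pairs, cfg)
  expect_equal(nrow(fit$log), 2L)
  expect_true(all(is.finite(unlist(
    fit$log[c("loss_d", "loss_g_adv", "loss_g_l2", "hybrid", "sat_frac")]))))
  expect_true(all(fit$log$sat_frac >= 0 & fit$log$sat_frac <= 1))
})

test_that("training is deterministic under a fixed seed", {
  pairs <- tiny_dataset(n = 4L, extent = 16L)
  cfg <- tiny_cfg(extent = 16L, epochs = 2L, seed = 6L)
  f1 <- egan_train(pairs, cfg)
  f2 <- egan_train(pairs, cfg)
  expect_identical(f1$log$hybrid, f2$log$hybrid)
  expect_identical(f1$gen$params, f2$gen$params)
})

test_that("checkpoint resume continues the identical RNG stream", {
  pairs <- tiny_dataset(n = 4L, extent = 16L)
  out <- file.path(tempdir(), "ckpt_run")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- tiny_cfg(extent = 16L, epochs = 4L, seed = 7L)
  full <- egan_train(pairs, cfg, out_dir = out)

  ck2 <- file.path(out, "ckpt_epoch0002.rds")
  expect_true(file.exists(ck2))
  resumed <- egan_train(pairs, cfg, resume = ck2)
  expect_equal(nrow(resumed$log), 4L)
  expect_identical(resumed$log$hybrid, full$log$hybrid)
  expect_identical(resumed$gen$params, full$gen$params)
  expect_identical(resumed$disc$params, full$disc$params)
})

test_that("invalid datasets abort before any optimization", {
  pairs <- tiny_dataset(n = 2L, extent = 16L)
  cfg <- tiny_cfg(extent = 16L)
  bad <- pairs
  bad[[1]] <- list(pet = bad[[1]]$pet$data[, , 1:8], mri = bad[[1]]$mri$data)
  expect_error(egan_train(bad, cfg), "mismatch")

  unscaled <- lapply(pairs, function(p)
    list(pet = p$pet$data * 5, mri = p$mri$data))
  expect_error(egan_train(unscaled, cfg), "preprocess")

  wrong_size <- lapply(pairs, function(p)
    list(pet = p$pet$data[1:8, 1:8, 1:8], mri = p$mri$data[1:8, 1:8, 1:8]))
  expect_error(egan_train(wrong_size, cfg), "expected")
})

test_that("loss variants reproduce the objective ablation axes", {
  pairs <- tiny_dataset(n = 2L, extent = 16L)
  # L2-only: no discriminator updates, loss_d stays 0
  cfg_mse <- tiny_cfg(extent = 16L, epochs = 1L, loss_variant = "mse")
  fit_mse <- egan_train(pairs, cfg_mse)
  expect_equal(fit_mse$log$loss_d, 0)
  expect_equal(fit_mse$log$loss_g_adv, 0)

  # saturating (KL-style) generator loss is negative at a fooled D
  cfg_kl <- tiny_cfg(extent = 16L, epochs = 1L, loss_variant = "kl")
  fit_kl <- egan_train(pairs, cfg_kl)
  expect_true(is.finite(fit_kl$log$loss_g_adv))
  expect_lt(fit_kl$log$loss_g_adv, 0)  # log(1 - d_fake) < 0
})

test_that("validation split tracks a finite held-out L2", {
  pairs <- tiny_dataset(n = 5L, extent = 16L)
  cfg <- tiny_cfg(extent = 16L, epochs = 2L)
  fit <- egan_train(pairs, cfg, val_fraction = 0.2)
  expect_true(all(is.finite(fit$log$val_l2)))
  expect_error(egan_train(pairs[1], cfg, val_fraction = 0.9), "no training")
})
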