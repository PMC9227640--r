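cfg16 <- tiny_cfg(extent = 16L)

test_that("generator maps a preprocessed volume to the same grid in (-1, 1)", {
  set.seed(81)
  gen <- generator_init(cfg16)
  pet <- array(tanh(rnorm(16^3)), c(16, 16, 16))
  out <- generator_forward(pet, gen, cfg16)
  expect_identical(dim(out$data), c(16L, 16L, 16L))
  expect_true(all(out$data > -1 & out$data < 1))

  # eval-mode determinism is bitwise
  out2 <- generator_forward(pet, gen, cfg16)
  expect_identical(out$data, out2$data)

  # out-of-range input is flagged
  expect_warning(generator_forward(pet * 3, gen, cfg16), "range")
  expect_error(generator_forward(pet * 3, gen, cfg16, range_check = "error"),
               "range")

  # all-zero parameters force tanh(0) = 0 everywhere
  gen0 <- gen
  gen0$params <- egan3d:::tree_map(function(x) x * 0, gen0$params)
  expect_equal(generator_forward(pet, gen0, cfg16)$data,
               array(0, c(16, 16, 16)))
})

test_that("decoder input assembly tiles the fused map and convolves the edge channel", {
  set.seed(82)
  l <- matrix(runif(16 * 16), 16)
  fused <- list(g = l, l = l)
  post <- list(w = array(0, c(3, 3, 3, 1, 1)), b = 0)
  post$w[2, 2, 2, 1, 1] <- 1  # identity kernel
  edge <- array(0.7, c(16, 16, 16))
  x <- assemble_decoder_input(fused, edge, post, 16L)
  expect_identical(dim(x), c(16L, 16L, 16L, 2L))
  for (z in c(1, 8, 16))
    expect_equal(x[, , z, 1], l)                     # axial tiling
  expect_equal(x[, , , 2], edge, tolerance = 1e-12)  # conv of constant

  x0 <- assemble_decoder_input(list(l = l * 0), edge, post, 16L)
  expect_equal(x0[, , , 1], array(0, c(16, 16, 16)))

  xa <- assemble_decoder_input(fused, NULL, post, 16L)
  expect_equal(xa[, , , 2], array(0, c(16, 16, 16)))

  expect_error(assemble_decoder_input(list(l = matrix(0, 8, 8)), edge, post,
                                      16L), "extent")
})

test_that("discriminator returns a conditional probability strictly inside (0, 1)", {
  set.seed(83)
  disc <- discriminator_init(cfg16)
  a <- array(tanh(rnorm(16^3)), c(16, 16, 16))
  b <- array(tanh(rnorm(16^3)), c(16, 16, 16))
  p <- discriminate(a, b, disc, cfg16)
  expect_true(p > 0 && p < 1)
  expect_identical(discriminate(a, b, disc, cfg16), p)

  disc0 <- disc
  disc0$params <- egan3d:::tree_map(function(x) x * 0, disc0$params)
  expect_equal(discriminate(a, b, disc0, cfg16), 0.5)

  # conditional on the source: changing the PET channel moves the output
  expect_false(discriminate(b, b, disc, cfg16) == p)
  expect_error(discriminate(a, array(0, c(16, 16, 8)), disc, cfg16), "differ")
})

test_that("ablating the Sobel channel changes the generator output", {
  set.seed(84)
  gen <- generator_init(cfg16)
  pet <- array(tanh(rnorm(16^3)), c(16, 16, 16))
  full <- generator_forward(pet, gen, cfg16)
  abl <- generator_forward(pet, gen, cfg16, ablate_sobel = TRUE)
  expect_gt(max(abs(full$data - abl$data)), 1e-8)
})

test_that("one optimization step reaches every parameter tensor (no detached subgraph)", {
  cfg <- tiny_cfg(extent = 16L, epochs = 1L)
  set.seed(85)
  gen <- generator_init(cfg)
  disc <- discriminator_init(cfg)
  pets <- lapply(1:2, function(i) array(tanh(rnorm(16^3)), c(16, 16, 16)))
  mris <- lapply(1:2, function(i) array(tanh(rnorm(16^3)), c(16, 16, 16)))
  edges <- lapply(pets, function(p) apply_sobel(p)$data)

  fw <- egan3d:::generator_forward_batch(pets, edges, gen, cfg, train = TRUE)
  gouts <- vector("list", 2)
  dgrads <- egan3d:::tree_zero_like(disc$params)
  for (b in 1:2) {
    ff <- egan3d:::disc_forward_one(pets[[b]], fw$out[[b]], disc$params, cfg,
                                    cache = TRUE)
    db <- egan3d:::disc_backward_one(-1 / ff$prob, disc$params, ff$cache, cfg,
                                     need_gx = TRUE)
    dgrads <- egan3d:::tree_add(dgrads, db$grads)
    diff <- fw$out[[b]] - mris[[b]]
    gouts[[b]] <- array(db$gx[, , , 2], dim(diff)) + diff / length(diff)
  }
  ggrads <- egan3d:::generator_backward_batch(gouts, gen, fw$cache, cfg)

  leaf_norms <- function(tree) vapply(
    rapply(tree, function(x) sum(abs(x)), how = "unlist"), identity,
    numeric(1))
  expect_true(all(leaf_norms(ggrads) > 0))
  expect_true(all(leaf_norms(dgrads) > 0))
})
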