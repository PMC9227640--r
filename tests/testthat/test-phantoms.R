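test_that("phantom generation is deterministic under its seed", {
  spec <- phantom_spec(extent = 16L, seed = 7L)
  a <- make_paired_phantom(spec)
  b <- make_paired_phantom(spec)
  expect_identical(a$pair$pet$data, b$pair$pet$data)
  expect_identical(a$pair$mri$data, b$pair$mri$data)
  expect_identical(a$labels, b$labels)
})

test_that("noise-free, blur-free phantoms are exact tissue remaps", {
  spec <- phantom_spec(extent = 16L, noise_sigma = 0, smoothing_sigma = 0,
                       seed = 8L)
  ph <- make_paired_phantom(spec)
  pet_map <- c(0, spec$pet_weights)[ph$labels + 1L]
  mri_map <- c(0, spec$tissue_intensities)[ph$labels + 1L]
  expect_equal(as.numeric(ph$pair$pet$data), pet_map, tolerance = 1e-12)
  expect_equal(as.numeric(ph$pair$mri$data), mri_map, tolerance = 1e-12)
})

test_that("grey-matter volume fraction stays in a plausible band across seeds", {
  fracs <- vapply(1:100, function(s) {
    ph <- make_paired_phantom(phantom_spec(extent = 16L, seed = 1000L + s))
    head <- ph$labels > 0L
    sum(ph$labels == 2L) / sum(head)
  }, numeric(1))
  expect_gte(min(fracs), 0.05)
  expect_lte(max(fracs), 0.60)
})

test_that("pseudo-PET and pseudo-MRI are positively correlated (task is learnable)", {
  for (s in 1:20) {
    ph <- make_paired_phantom(phantom_spec(extent = 16L, seed = 2000L + s))
    expect_gt(norm_xcorr(ph$pair$pet, ph$pair$mri), 0.3)
  }
})

test_that("distinct seeds give distinct geometries", {
  labs <- lapply(1:20, function(s)
    make_paired_phantom(phantom_spec(extent = 12L, seed = 3000L + s))$labels)
  for (i in 1:19) for (j in (i + 1):20)
    expect_false(identical(labs[[i]], labs[[j]]))
})

test_that("dataset writer emits NIfTI pairs plus a manifest and refuses collisions", {
  out <- file.path(tempdir(), "phantom_ds")
  on.exit(unlink(out, recursive = TRUE))
  ds <- make_dataset(4, phantom_spec(extent = 12L, seed = 40L), out_dir = out)
  files <- list.files(out, pattern = "\\.nii\\.gz$")
  expect_length(files, 8L)
  expect_equal(nrow(ds$manifest), 4L)
  expect_error(make_dataset(2, phantom_spec(extent = 12L, seed = 41L),
                            out_dir = out), "refusing")
})

test_that("preprocessing a phantom dataset yields training-ready pairs", {
  pp <- tiny_dataset(n = 2L, extent = 16L)
  for (p in pp) {
    expect_identical(dim(p$pet$data), c(16L, 16L, 16L))
    expect_equal(range(p$pet$data), c(-1, 1))
    expect_equal(range(p$mri$data), c(-1, 1))
  }
})
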