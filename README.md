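# egan3d — separable-convolution adversarial translation of FDG-PET into T1 MRI

`egan3d` synthesizes a 3D T1-weighted MRI volume from a co-registered FDG-PET
volume with a conditional GAN whose generator is deliberately *not* a full 3D
convolutional encoder:

* a **separable-convolution encoder** collapses the PET volume into three 2D
  feature maps, one per anatomical view (sagittal/coronal/axial), using an
  axis-spanning long-range branch and a strided local branch per view;
* the maps are mixed by a **tanh-normalized Hadamard fusion**
  `g_ij = tanh(x_ij · yᵀ_ij) / Σ_i' tanh(x_i'j · yᵀ_i'j)` (then the third view
  by the same rule), an attention-like step without learned projections;
* a fixed **3×3×3 Sobel operator** supplies the geometric information the 2D
  features lose — the gradient-magnitude volume enters the decoder as a second
  channel through a small learnable scale-fixing convolution;
* a four-layer 3D convolutional **decoder** (BatchNorm + LeakyReLU, final
  tanh) reconstructs the MRI; a 3D fully convolutional **discriminator**
  judges (PET, MRI) pairs;
* training minimizes the weighted hybrid objective
  `α₁·L_GAN + α₂·L2` with `α₁ = 1, α₂ = 0.5`, the non-saturating adversarial
  form (whose optimum is the Jensen–Shannon divergence, exposed as `jsd()`),
  Adam (lr 1e-4, β = (0.5, 0.999)), and N(0, 0.02) initialization.

The package also implements the full intrinsic evaluation suite — PSNR, SSIM
(3D Gaussian window), MAE, normalized cross-correlation, 3D grey-level
co-occurrence matrices with Haralick features (8 levels, distance 3, 60°
in-plane direction = offset (2,3,0)), and three-class tissue analysis — plus
a paired ellipsoid head-phantom generator so that training, translation and
every metric run at desk scale with no clinical data. It is aimed at
researchers studying cross-modality neuroimage synthesis who want a fully
inspectable, dependency-light reference implementation.

Everything is implemented in R with small C++ kernels (explicit forward and
backward passes for every layer; no deep-learning framework required).

## Worked example

```r
library(egan3d)

# a paired phantom cohort: pseudo-PET is a smoothed, GM-weighted, noisy
# rendering of the pseudo-MRI, on identical geometry
spec <- phantom_spec(extent = 32L, seed = 42L)
ds <- make_dataset(8, spec)
pairs <- preprocess_dataset(ds$pairs, 32L)

# the geometric channel the generator receives
print(apply_sobel(pairs[[1]]$pet))
#> <volume> 32x32x32 voxels, spacing 1x1x1 mm, range [0.0059106, 15.511]

# the no-learning baseline: score the pseudo-PET itself against the MRI
to01 <- function(v) (v$data + 1) / 2
print(evaluate_pair(to01(pairs[[7]]$pet), to01(pairs[[7]]$mri), data_range = 1))
#> PSNR 18.021 dB | SSIM 0.5034 | MAE 0.09826 | XCorr 0.9016
```

The PSNR line reads: treating the pseudo-PET as if it were the MRI is 18 dB
away from the truth — that is the bar a trained generator has to clear.

The end-to-end desk-scale experiment (16 training phantoms, 4 held out,
200 epochs, with a Sobel-ablated twin) is one call; a single seed takes a
few minutes on one core:

```r
res <- phantom_translation_study(seeds = 1)
print(res[, c("l2_first", "l2_final", "psnr_baseline", "psnr_full",
              "psnr_ablated", "sat_frac_full", "sat_frac_ablated")], digits = 3)
#>   l2_first l2_final psnr_baseline psnr_full psnr_ablated sat_frac_full
#> 1    0.618   0.0384            18      19.8         14.3             0
#>   sat_frac_ablated
#> 1          0.00179
```

Read across the row: the generator's L2 term collapses from 0.62 to 0.04
during training; the translated volumes beat the 18 dB pseudo-PET baseline;
and ablating the Sobel channel costs about 5.5 dB of held-out PSNR — the
geometric channel is what lets the decoder place tissue boundaries. The two
`sat_frac` columns report the discriminator-saturation monitor
(fraction of batches with `D(fake) < 1e-3`). Averaging over three seeds
(`seeds = 1:3`, as the test suite does) puts the full model's PSNR gain
near +4 dB over the baseline.

## Command line

```sh
Rscript inst/cli/egan3d.R phantom --out data --n 16 --extent 32 --seed 7
Rscript inst/cli/egan3d.R train --manifest data/manifest.tsv --out run --profile desk
Rscript inst/cli/egan3d.R translate --checkpoint run/last.rds --in pet.nii.gz --out mri_hat.nii.gz
Rscript inst/cli/egan3d.R evaluate --gen gen_dir --real real_dir --out report.json
Rscript inst/cli/egan3d.R sobel --in vol.nii.gz --out edges.nii.gz
```

The `paper` profile preserves the published training recipe verbatim (90³
volumes, decoder channels 64/32/16, batch 12, 1000 epochs, lr 1e-4); `desk`
is the CPU-scale configuration used by the tests. See
`vignettes/egan3d-methods.Rmd` for the model, every tunable parameter, and
the design decisions.

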