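# Paired pseudo-PET / pseudo-MRI head phantoms: a nested-ellipsoid "head"
# (outer CSF shell, GM shell, WM core) with per-subject random semi-axes and
# rotation. The MRI renders the tissue intensity map plus Gaussian noise;
# the PET applies GM-dominant uptake weights to the same tissue map, then
# Gaussian smoothing (the scanner's point-spread blur) and noise. The pair
# is geometrically aligned by construction and the generating label map is
# exact tissue ground truth, so translation, tissue analysis and texture
# metrics all run at desk scale without clinical data.

#' Phantom specification
#'
#' @param extent cubic grid side (default 32, the desk scale).
#' @param tissue_intensities MRI intensities for (CSF, GM, WM); must be
#'   strictly increasing (T1 contrast). Background is 0.
#' @param pet_weights PET uptake for (CSF, GM, WM); grey matter must
#'   dominate (`GM > WM > CSF`), mirroring FDG metabolism.
#' @param smoothing_sigma PET blur in voxels (default 1.5).
#' @param noise_sigma additive Gaussian noise s.d. on both modalities
#'   (default 0.02, on the unit intensity scale).
#' @param seed base RNG seed; each subject uses `seed + i - 1`.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(extent = 32L,
                         tissue_intensities = c(csf = 0.12, gm = 0.55, wm = 0.85),
                         pet_weights = c(csf = 0.15, gm = 1.0, wm = 0.40),
                         smoothing_sigma = 1.5, noise_sigma = 0.02,
                         seed = 1L) {
  stopifnot(extent >= 8L,
            length(tissue_intensities) == 3L, length(pet_weights) == 3L,
            all(diff(tissue_intensities) > 0),
            pet_weights[2] > pet_weights[3], pet_weights[3] > pet_weights[1],
            smoothing_sigma >= 0, noise_sigma >= 0)
  structure(list(extent = as.integer(extent),
                 tissue_intensities = unname(tissue_intensities),
                 pet_weights = unname(pet_weights),
                 smoothing_sigma = smoothing_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate one paired phantom
#'
#' @param spec a [phantom_spec()].
#' @param subject_id identifier (defaults to one derived from the seed).
#' @return List with `pair` (a [paired_sample()]) and `labels` (integer
#'   array: 0 background, 1 CSF, 2 GM, 3 WM).
#' @export
make_paired_phantom <- function(spec = phantom_spec(), subject_id = NULL) {
  E <- spec$extent
  set.seed(spec$seed)
  if (is.null(subject_id)) subject_id <- sprintf("phantom%05d", spec$seed)
  for (attempt in seq_len(20L)) {
    center <- (E + 1) / 2 + runif(3, -1, 1) * 0.03 * E
    semi_out <- E / 2 * 0.82 * runif(3, 0.9, 1.05)
    f_gm <- runif(1, 0.75, 0.85)   # GM shell outer boundary, fraction of CSF
    f_wm <- runif(1, 0.60, 0.75)   # WM core, fraction of GM boundary
    R <- random_rotation()
    co <- as.matrix(expand.grid(x = seq_len(E), y = seq_len(E), z = seq_len(E)))
    rel <- (co - matrix(center, nrow(co), 3, byrow = TRUE)) %*% R
    qform <- function(semi) rowSums(sweep(rel, 2, semi, "/")^2)
    q_out <- qform(semi_out)
    q_gm <- qform(semi_out * f_gm)
    q_wm <- qform(semi_out * f_gm * f_wm)
    labels <- integer(nrow(co))
    labels[q_out <= 1] <- 1L
    labels[q_gm <= 1] <- 2L
    labels[q_wm <= 1] <- 3L
    labels <- array(labels, c(E, E, E))
    if (all(tabulate(labels + 1L, 4L) > 0L)) break
    if (attempt == 20L)
      stop("make_paired_phantom: could not sample nested shells with all tissues present")
  }
  mri_map <- array(c(0, spec$tissue_intensities)[labels + 1L], c(E, E, E))
  pet_map <- array(c(0, spec$pet_weights)[labels + 1L], c(E, E, E))
  mri <- mri_map
  pet <- if (spec$smoothing_sigma > 0)
    gaussian_filter3(pet_map, spec$smoothing_sigma) else pet_map
  if (spec$noise_sigma > 0) {
    mri <- mri + array(rnorm(E^3, 0, spec$noise_sigma), c(E, E, E))
    pet <- pet + array(rnorm(E^3, 0, spec$noise_sigma), c(E, E, E))
  }
  pet <- pmax(pet, 0)  # tracer counts are non-negative
  list(pair = paired_sample(as_volume(pet), as_volume(mri),
                            subject_id = subject_id),
       labels = labels)
}

#' Generate a phantom dataset
#'
#' Subjects use consecutive seeds `spec$seed .. spec$seed + n - 1`. When
#' `out_dir` is given, each pair is written as NIfTI
#' (`<id>_pet.nii.gz`, `<id>_mri.nii.gz`) with a `manifest.tsv` readable by
#' [read_manifest()].
#'
#' @param n number of subjects (>= 1).
#' @param spec a [phantom_spec()].
#' @param out_dir optional output directory; must not already contain a
#'   manifest.
#' @return List with `pairs` (list of [paired_sample()]), `labels` (list of
#'   label arrays) and `manifest` (data frame; `NULL` paths unless written).
#' @export
make_dataset <- function(n, spec = phantom_spec(), out_dir = NULL) {
  stopifnot(n >= 1)
  pairs <- vector("list", n); labels <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "manifest.tsv")))
      stop("make_dataset: ", file.path(out_dir, "manifest.tsv"),
           " already exists; refusing to overwrite")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    si <- spec; si$seed <- spec$seed + i - 1L
    ph <- make_paired_phantom(si)
    pairs[[i]] <- ph$pair; labels[[i]] <- ph$labels
    id <- ph$pair$subject_id
    if (!is.null(out_dir)) {
      pp <- file.path(out_dir, paste0(id, "_pet.nii.gz"))
      mp <- file.path(out_dir, paste0(id, "_mri.nii.gz"))
      write_volume(ph$pair$pet, pp)
      write_volume(ph$pair$mri, mp)
      rows[[i]] <- data.frame(subject_id = id, pet_path = basename(pp),
                              mri_path = basename(mp))
    } else {
      rows[[i]] <- data.frame(subject_id = id, pet_path = NA_character_,
                              mri_path = NA_character_)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  list(pairs = pairs, labels = labels, manifest = manifest)
}

#' Preprocess a phantom dataset for training
#'
#' Applies the modality-specific preprocessing chains ([preprocess_pet()],
#' [preprocess_mri()]) to every pair at the configured extent.
#'
#' @param pairs list of [paired_sample()].
#' @param extent target cubic extent.
#' @return List of preprocessed `paired_sample` objects in \[-1, 1\].
#' @export
preprocess_dataset <- function(pairs, extent = 32L) {
  target <- rep(as.integer(extent), 3L)
  lapply(pairs, function(p)
    paired_sample(preprocess_pet(p$pet, target),
                  preprocess_mri(p$mri, target),
                  subject_id = p$subject_id))
}
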