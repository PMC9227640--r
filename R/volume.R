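#' 3D volume container
#'
#' A `volume` is the package's universal currency: a 3D numeric array plus
#' voxel spacing (mm) and a 4x4 affine mapping voxel indices to world
#' coordinates. Volumes are assumed co-registered upstream (e.g. to MNI
#' space); this package performs no spatial registration.
#'
#' @param data 3D numeric array, every dimension at least 3, all values finite.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param affine 4x4 numeric matrix; defaults to a scaling affine built from
#'   `spacing`.
#' @return An object of class `volume` with elements `data`, `spacing`,
#'   `affine`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (inherits(data, "volume")) return(data)
  data <- unclass(data)
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         if (is.null(dim(data))) "a vector" else paste0(length(dim(data)), "D"))
  if (any(dim(data) < 3L))
    stop("all volume dimensions must be >= 3, got ",
         paste(dim(data), collapse = "x"))
  storage.mode(data) <- "double"
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s) (NaN/Inf)")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, range [", signif(min(x$data), 5), ", ", signif(max(x$data), 5),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

# Accept either a volume or a bare 3D array in user-facing functions.
vol_data <- function(v) if (inherits(v, "volume")) v$data else as_volume(v)$data

#' Read a NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file, widens intensities to double precision and
#' validates that the image is 3D and free of non-finite voxels.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [as_volume()] object.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  affine <- unclass(RNifti::xform(img))
  as_volume(array(as.numeric(img), dim = d), spacing = spacing,
            affine = matrix(as.numeric(affine), 4, 4))
}

#' Write a volume as NIfTI
#'
#' @param v a [as_volume()] object or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  img <- RNifti::asNifti(
    v$data,
    reference = list(pixdim = c(1, v$spacing, 0, 0, 0, 0),
                     srow_x = v$affine[1, ], srow_y = v$affine[2, ],
                     srow_z = v$affine[3, ], sform_code = 2L),
    datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pair of co-registered PET/MRI volumes
#'
#' @param pet,mri [as_volume()] objects on the same grid.
#' @param subject_id character identifier.
#' @param tol tolerance for the affine agreement check.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(pet, mri, subject_id = "subject", tol = 1e-4) {
  pet <- as_volume(pet); mri <- as_volume(mri)
  if (!identical(dim(pet$data), dim(mri$data)))
    stop("pet and mri shapes differ: ", paste(dim(pet$data), collapse = "x"),
         " vs ", paste(dim(mri$data), collapse = "x"))
  if (max(abs(pet$affine - mri$affine)) > tol)
    stop("pet and mri affines differ beyond tolerance ", tol)
  structure(list(pet = pet, mri = mri, subject_id = subject_id),
            class = "paired_sample")
}

#' Read a dataset manifest
#'
#' The manifest is a TSV with columns `subject_id`, `pet_path`, `mri_path`;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @param load if `TRUE`, load every pair into [paired_sample()] objects.
#' @return A data frame, or a list of `paired_sample` when `load = TRUE`.
#' @export
read_manifest <- function(path, load = FALSE) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "pet_path", "mri_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  if (!load) return(man)
  lapply(seq_len(nrow(man)), function(i)
    paired_sample(load_volume(resolve(man$pet_path[i])),
                  load_volume(resolve(man$mri_path[i])),
                  subject_id = man$subject_id[i]))
}
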