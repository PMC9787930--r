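#' 3D intensity volume with physical geometry
#'
#' The unit of data flowing through the pipeline: a 3D grid of intensities
#' together with its voxel spacing in mm, its anatomical orientation
#' (direction cosines of the three grid axes in DICOM LPS patient space),
#' the MRI modality and a patient identifier. Grid indexing is
#' (row, column, slice).
#'
#' @param grid 3D numeric array of finite intensities.
#' @param spacing numeric length-3, voxel edge lengths `(sx, sy, sz)` in mm,
#'   all positive.
#' @param orientation 3x3 matrix whose k-th column is the LPS direction of
#'   grid axis k. Defaults to the sagittal standard.
#' @param modality one of `"FLAIR"`, `"T1w"`, `"T1wCE"`, `"T2w"`, `"mask"`.
#' @param patient_id opaque identifier string.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(grid, spacing = c(1, 1, 1),
                         orientation = sagittal_orientation(),
                         modality = "FLAIR", patient_id = "anon") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("'grid' must be a 3D array")
  storage.mode(grid) <- "double"
  vol <- structure(
    list(grid = grid, spacing = as.numeric(spacing),
         orientation = orientation, modality = modality,
         patient_id = patient_id),
    class = "brain_volume")
  validate_volume(vol)
  vol
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<brain_volume> %s, patient %s\n", x$modality, x$patient_id))
  cat(sprintf("  grid %d x %d x %d, spacing %.3g x %.3g x %.3g mm, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              orientation_tag(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$grid), max(x$grid)))
  invisible(x)
}

validate_volume <- function(vol) {
  stopifnot(inherits(vol, "brain_volume"))
  if (length(vol$spacing) != 3L || any(!is.finite(vol$spacing)) ||
      any(vol$spacing <= 0))
    stop("spacing components must be positive and finite")
  if (any(!is.finite(vol$grid)))
    stop("volume grid contains non-finite values")
  if (any(dim(vol$grid) < 1L))
    stop("every grid dimension must be >= 1")
  o <- vol$orientation
  if (!is.matrix(o) || any(dim(o) != c(3L, 3L)))
    stop("orientation must be a 3x3 direction-cosine matrix")
  if (any(abs(sqrt(colSums(o^2)) - 1) > 1e-4))
    stop("orientation columns must be unit vectors")
  invisible(vol)
}

#' Sagittal-standard orientation matrix
#'
#' Grid rows run along +y (anterior to posterior), columns along -z
#' (superior to inferior), slices along +x (right to left) in LPS space —
#' the DICOM sagittal convention.
#' @return 3x3 direction-cosine matrix.
#' @export
sagittal_orientation <- function() {
  cbind(c(0, 1, 0), c(0, 0, -1), c(1, 0, 0))
}

#' Named anatomical orientation of a volume
#'
#' Classifies the stacking (slice) axis of the grid: `sagittal` when slices
#' advance along the patient x axis, `coronal` along y, `axial` along z, and
#' `oblique` otherwise.
#' @param vol a [brain_volume].
#' @return character scalar.
#' @export
orientation_tag <- function(vol) {
  k <- vol$orientation[, 3]
  ax <- which.max(abs(k))
  if (abs(k[ax]) < 0.99) return("oblique")
  c("sagittal", "coronal", "axial")[ax]
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti keeping the voxel spacing. The anatomical
#' orientation of `kbfmgmt` volumes is carried separately and defaults to
#' the sagittal standard on read.
#' @param vol a [brain_volume].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality,patient_id metadata attached on read.
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a [brain_volume].
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, modality = "FLAIR", patient_id = "anon") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  grid <- array(as.numeric(img), dim = dim(img)[1:3])
  brain_volume(grid, spacing = sp, modality = modality,
               patient_id = patient_id)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#' @param a,b logical/0-1 arrays of identical shape.
#' @return numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a != 0; b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
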