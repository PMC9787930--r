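# Synthetic brain phantoms: seeded, paired FLAIR / T1-w volumes with
# ground-truth tumor masks that instantiate exactly the intensity
# assumptions the ROI filter relies on — tumor voxels are the brightest
# tissue in FLAIR and sit between CSF and parenchyma in T1-w. The
# methylation label modulates the internal texture of the tumor (not its
# mean intensity), so the ROI filter stays label-agnostic and a classifier
# must exploit within-ROI structure.

#' Phantom generation parameters
#'
#' @param grid_side cubic grid side in voxels. The default (64 at 1 mm) is
#'   a fast preset; `grid_side = 192` reproduces the full-scale geometry.
#' @param spacing voxel spacing in mm.
#' @param brain_axes ellipsoid semi-axes of the brain, voxels.
#' @param csf_fraction approximate fraction of the brain occupied by the
#'   two CSF (ventricle) cavities.
#' @param tumor_count number of tumor blobs (0 for a tumor-free phantom).
#' @param tumor_radius_range min/max tumor radius, voxels.
#' @param flair_means,flair_sds,t1_means,t1_sds class intensity means and
#'   SDs, in order (background, csf, parenchyma, tumor). The means must
#'   satisfy the modality orderings: FLAIR tumor brightest; T1
#'   CSF < tumor < parenchyma.
#' @param label_effect amplitude of the methylation-conditional smooth
#'   heterogeneity field added to FLAIR tumor voxels of positive phantoms
#'   (intensity units; 0 decouples labels from images).
#' @param noise_sd global additive Gaussian noise SD.
#' @param prevalence probability that a phantom is methylation-positive
#'   when no label is forced.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(grid_side = 64L, spacing = c(1, 1, 1),
                           brain_axes = round(grid_side * c(0.42, 0.38, 0.33)),
                           csf_fraction = 0.06, tumor_count = 1L,
                           tumor_radius_range = round(grid_side * c(0.09, 0.13)),
                           flair_means = c(background = 0, csf = 60,
                                           parenchyma = 100, tumor = 180),
                           flair_sds = c(0, 8, 10, 12),
                           t1_means = c(background = 0, csf = 40,
                                        parenchyma = 110, tumor = 70),
                           t1_sds = c(0, 8, 10, 8),
                           label_effect = 35, noise_sd = 4,
                           prevalence = 0.5) {
  if (!(flair_means[4] > flair_means[3] && flair_means[4] > flair_means[2]))
    stop("FLAIR means must make tumor the brightest tissue class")
  if (!(t1_means[2] < t1_means[4] && t1_means[4] < t1_means[3]))
    stop("T1-w means must order CSF < tumor < parenchyma")
  if (any(c(flair_sds, t1_sds) < 0) || noise_sd < 0)
    stop("standard deviations must be >= 0")
  structure(list(grid_side = as.integer(grid_side), spacing = spacing,
                 brain_axes = brain_axes, csf_fraction = csf_fraction,
                 tumor_count = as.integer(tumor_count),
                 tumor_radius_range = tumor_radius_range,
                 flair_means = flair_means, flair_sds = flair_sds,
                 t1_means = t1_means, t1_sds = t1_sds,
                 label_effect = label_effect, noise_sd = noise_sd,
                 prevalence = prevalence),
            class = "phantom_params")
}

# Smooth unit-SD random field: coarse white noise trilinearly upsampled.
smooth_field <- function(d, coarse = 8L) {
  cd <- pmax(2L, ceiling(d / coarse))
  co <- array(rnorm(prod(cd)), dim = cd)
  pts <- grid_coords(d, scale = (d - 1) / (cd - 1))
  f <- array(trilinear_sample(co, pts, fill = 0), dim = d)
  (f - mean(f)) / max(sd(f), 1e-12)
}

#' Generate one synthetic brain phantom
#'
#' An ellipsoidal brain with two CSF cavities and `tumor_count` spherical
#' tumor blobs, rendered in FLAIR and T1-w with Gaussian class noise and
#' global noise, rounded to integer intensities (the stored MR dialect).
#' The empirical class-mean orderings are asserted on every phantom. Fully
#' reproducible per seed.
#'
#' @param params a [phantom_params].
#' @param seed integer seed.
#' @param label force the methylation label (0/1); `NULL` draws it with
#'   the configured prevalence.
#' @return object of class `phantom`: `flair` and `t1` [brain_volume]s,
#'   `brain_mask`, logical `tumor_mask`, `label` and DICOM-style `meta`.
#' @export
make_phantom <- function(params = phantom_params(), seed = 1L,
                         label = NULL) {
  side <- params$grid_side
  d <- rep(side, 3L)
  with_seed(seed, {
    if (is.null(label)) label <- rbinom(1, 1, params$prevalence)
    ctr <- (d + 1) / 2
    ax <- lapply(1:3, function(a) seq_len(d[a]))
    dist2 <- function(center, semi) {
      u1 <- ((ax[[1]] - center[1]) / semi[1])^2
      u2 <- ((ax[[2]] - center[2]) / semi[2])^2
      u3 <- ((ax[[3]] - center[3]) / semi[3])^2
      outer(outer(u1, u2, `+`), u3, `+`)
    }
    brain <- dist2(ctr, params$brain_axes) <= 1
    s <- (params$csf_fraction / 2)^(1 / 3)
    off <- params$brain_axes[2] * 0.3
    csf <- (dist2(ctr + c(0, off, 0), params$brain_axes * s) <= 1 |
            dist2(ctr - c(0, off, 0), params$brain_axes * s) <= 1) & brain
    tumor <- array(FALSE, d)
    for (t in seq_len(params$tumor_count)) {
      r <- runif(1, params$tumor_radius_range[1],
                 params$tumor_radius_range[2])
      repeat {
        u <- runif(3, -0.55, 0.55)
        cen <- ctr + u * params$brain_axes
        if (sum((u * params$brain_axes / (params$brain_axes - r))^2) < 1)
          break
      }
      tumor <- tumor | dist2(cen, rep(r, 3)) <= 1
    }
    tumor <- tumor & brain
    csf <- csf & !tumor
    paren <- brain & !csf & !tumor
    render <- function(means, sds) {
      g <- array(0, d)
      n <- sum(paren); g[paren] <- rnorm(n, means[3], sds[3])
      n <- sum(csf); g[csf] <- rnorm(n, means[2], sds[2])
      n <- sum(tumor); g[tumor] <- rnorm(n, means[4], sds[4])
      g
    }
    flair <- render(params$flair_means, params$flair_sds)
    t1 <- render(params$t1_means, params$t1_sds)
    if (label == 1 && any(tumor) && params$label_effect > 0) {
      f <- smooth_field(d, coarse = max(2L, side %/% 12L))
      ft <- f[tumor]
      ft <- (ft - mean(ft)) / max(sd(ft), 1e-12)
      flair[tumor] <- flair[tumor] + params$label_effect * ft
    }
    if (params$noise_sd > 0) {
      flair <- flair + rnorm(length(flair), 0, params$noise_sd)
      t1 <- t1 + rnorm(length(t1), 0, params$noise_sd)
    }
    flair <- round(pmax(flair, 0)); t1 <- round(pmax(t1, 0))
    # empirical intensity-ordering guarantees the ROI filter relies on
    if (any(tumor)) {
      stopifnot(mean(flair[tumor]) > mean(flair[paren]),
                mean(flair[tumor]) > mean(flair[csf]),
                mean(t1[csf]) < mean(t1[tumor]),
                mean(t1[tumor]) < mean(t1[paren]))
    }
    pid <- sprintf("phantom%06d", seed %% 1000000L)
    structure(
      list(flair = brain_volume(flair, spacing = params$spacing,
                                modality = "FLAIR", patient_id = pid),
           t1 = brain_volume(t1, spacing = params$spacing,
                             modality = "T1w", patient_id = pid),
           brain_mask = brain_mask(brain * 1, source = "external"),
           tumor_mask = tumor, label = label,
           meta = list(pixel_spacing = params$spacing[1:2],
                       spacing_between_slices = params$spacing[3],
                       image_orientation = c(0, 1, 0, 0, 0, -1),
                       patient_id = pid),
           params = params, seed = seed),
      class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s: %d^3 voxels, label %d, %d tumor voxels\n",
    x$meta$patient_id, dim(x$flair$grid)[1], x$label, sum(x$tumor_mask)))
  invisible(x)
}

#' Generate a labeled phantom cohort
#'
#' `n` independent phantoms with exactly `round(prevalence * n)` positives,
#' shuffled; optionally written to disk as DICOM series (FLAIR and T1-w),
#' NIfTI ground-truth masks, a labels CSV and a JSON manifest.
#'
#' @param n cohort size (>= 2).
#' @param prevalence fraction of methylation-positive phantoms.
#' @param params a [phantom_params].
#' @param seed cohort seed (per-phantom seeds are derived from it).
#' @param out_dir optional output directory.
#' @return list with `phantoms` (list of [make_phantom] results) and
#'   `labels` (data.frame `patient_id`, `label`).
#' @export
make_cohort <- function(n, prevalence = 0.5, params = phantom_params(),
                        seed = 1L, out_dir = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  npos <- round(prevalence * n)
  labels <- seeds <- NULL
  with_seed(seed, {
    labels <- sample(c(rep(1L, npos), rep(0L, n - npos)))
    seeds <- sample.int(99999989L, n)
  })
  phantoms <- lapply(seq_len(n), function(i)
    make_phantom(params, seed = seeds[i], label = labels[i]))
  lab_df <- data.frame(
    patient_id = vapply(phantoms, function(p) p$meta$patient_id, ""),
    label = labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in phantoms) {
      pdir <- file.path(out_dir, p$meta$patient_id)
      write_dicom_series(p$flair, file.path(pdir, "FLAIR"))
      write_dicom_series(p$t1, file.path(pdir, "T1w"))
      write_volume_nifti(brain_volume(p$tumor_mask * 1,
                                      spacing = params$spacing,
                                      modality = "mask",
                                      patient_id = p$meta$patient_id),
                         file.path(pdir, "tumor_mask.nii.gz"))
      write_volume_nifti(brain_volume(p$brain_mask$grid * 1,
                                      spacing = params$spacing,
                                      modality = "mask",
                                      patient_id = p$meta$patient_id),
                         file.path(pdir, "brain_mask.nii.gz"))
    }
    write.csv(lab_df, file.path(out_dir, "labels.csv"), row.names = FALSE)
    manifest <- c(list(n = n, prevalence = prevalence, seed = seed),
                  unclass(params))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(phantoms = phantoms, labels = lab_df)
}
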