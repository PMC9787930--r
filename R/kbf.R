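# Knowledge-based filtering (KBF): unsupervised multimodal tumor-ROI
# preselection. Tumor tissue is FLAIR-bright and, on T1-w, darker than
# normal tissue but brighter than CSF; the filter therefore keeps the
# intersection of the brightest FLAIR tail above the FLAIR mode and the
# darkest T1-w tail below the T1-w mode.

#' KBF tuning parameters
#'
#' @param tail_fraction fraction in `(0, 0.5]` of the supra-/sub-mode voxels
#'   kept by the second (quantile) threshold. Default 0.25: the 25 percent
#'   highest FLAIR and 25 percent lowest T1-w values.
#' @param scope `"per_volume"` (default) runs the mode split, quantile
#'   thresholds and intersection once over the whole volume;
#'   `"per_slice"` repeats the full procedure independently on each 2D
#'   slice (third grid axis).
#' @param mode_bins histogram bin count used to locate the intensity mode of
#'   non-integer data; `NULL` (default) tabulates integer-valued data
#'   exactly and falls back to 256 bins otherwise.
#' @param crop_side side length in voxels of the output cube. Default 192.
#' @return object of class `kbf_params`.
#' @export
kbf_params <- function(tail_fraction = 0.25,
                       scope = c("per_volume", "per_slice"),
                       mode_bins = NULL, crop_side = 192L) {
  scope <- match.arg(scope)
  if (tail_fraction <= 0 || tail_fraction > 0.5)
    stop("tail_fraction must lie in (0, 0.5]")
  if (crop_side < 1) stop("crop_side must be >= 1")
  structure(list(tail_fraction = tail_fraction, scope = scope,
                 mode_bins = mode_bins, crop_side = as.integer(crop_side)),
            class = "kbf_params")
}

#' Binary ROI mask of KBF-preselected voxels
#'
#' @param grid logical/0-1 3D array.
#' @return object of class `roi_mask` with element `n_voxels`.
#' @export
roi_mask <- function(grid) {
  g <- array(grid != 0, dim = dim(grid))
  structure(list(grid = g, n_voxels = sum(g)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d selected voxels of %d (%.2f%%)\n",
              x$n_voxels, length(x$grid), 100 * x$n_voxels / length(x$grid)))
  invisible(x)
}

#' Most frequent intensity (mode)
#'
#' Integer-valued inputs are tabulated exactly; continuous inputs are binned
#' (`mode_bins` equal-width bins, bin centers reported). Ties are broken
#' toward the smallest value.
#'
#' @param values nonempty numeric vector (background zeros are expected to
#'   be excluded by the caller).
#' @param mode_bins bin count for continuous data; `NULL` for the default.
#' @return the modal intensity, a numeric scalar.
#' @export
intensity_mode <- function(values, mode_bins = NULL) {
  if (length(values) == 0L) stop("cannot take the mode of an empty set")
  if (all(abs(values - round(values)) < 1e-9)) {
    v <- as.integer(round(values))
    lo <- min(v)
    counts <- tabulate(v - lo + 1L)
    return(as.numeric(lo + which.max(counts) - 1L))
  }
  bins <- if (is.null(mode_bins)) 256L else as.integer(mode_bins)
  r <- range(values)
  if (diff(r) == 0) return(values[1])
  idx <- pmin(bins, 1L + floor((values - r[1]) / diff(r) * bins))
  k <- which.max(tabulate(idx, nbins = bins))
  r[1] + (k - 0.5) / bins * diff(r)
}

#' Split volumes at their intensity modes
#'
#' Marks in-brain FLAIR voxels strictly above the FLAIR mode and in-brain
#' T1-w voxels strictly below the T1-w mode; both modes are computed over
#' in-brain voxels only.
#'
#' @param flair,t1 aligned [brain_volume]s of the same shape.
#' @param brain a [brain_mask].
#' @param params a [kbf_params].
#' @return list with [roi_mask] elements `supra_flair` and `sub_t1`.
#' @export
mode_split <- function(flair, t1, brain, params = kbf_params()) {
  if (!identical(dim(flair$grid), dim(t1$grid)) ||
      !identical(dim(flair$grid), dim(brain$grid)))
    stop("FLAIR, T1-w and brain mask shapes differ")
  if (!any(brain$grid)) stop("empty brain: mask selects no voxels")
  fm <- intensity_mode(flair$grid[brain$grid], params$mode_bins)
  tm <- intensity_mode(t1$grid[brain$grid], params$mode_bins)
  list(supra_flair = roi_mask(brain$grid & flair$grid > fm),
       sub_t1 = roi_mask(brain$grid & t1$grid < tm))
}

#' Keep the top or bottom intensity quantile of a masked voxel set
#'
#' Of the `n` voxels selected by `mask`, keeps exactly
#' `k = ceiling(fraction * n)`: the `k` largest (`direction = "highest"`)
#' or smallest (`"lowest"`) by intensity. Intensity ties at the cut are
#' broken by ascending voxel index, so the result is deterministic.
#'
#' @param mask a [roi_mask] (an empty mask passes through).
#' @param values a [brain_volume] supplying the intensities.
#' @param fraction fraction in `(0, 1]` of voxels to keep.
#' @param direction `"highest"` or `"lowest"`.
#' @return a [roi_mask].
#' @export
quantile_select <- function(mask, values, fraction,
                            direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  idx <- which(mask$grid)
  out <- array(FALSE, dim(mask$grid))
  if (length(idx) > 0L) {
    k <- ceiling(fraction * length(idx))
    v <- values$grid[idx]
    ord <- if (direction == "highest") order(-v, idx) else order(v, idx)
    out[idx[ord[seq_len(k)]]] <- TRUE
  }
  roi_mask(out)
}

# Full KBF on plain arrays (any dimensionality): mode split, tail quantiles,
# cross-intersection.
kbf_core <- function(fl, t1, br, fraction, mode_bins) {
  out <- array(FALSE, dim(fl))
  if (!any(br)) return(out)
  fm <- intensity_mode(fl[br], mode_bins)
  tm <- intensity_mode(t1[br], mode_bins)
  sel <- function(cand, v, highest) {
    keep <- array(FALSE, dim(fl))
    idx <- which(cand)
    if (length(idx) == 0L) return(keep)
    k <- ceiling(fraction * length(idx))
    ord <- if (highest) order(-v[idx], idx) else order(v[idx], idx)
    keep[idx[ord[seq_len(k)]]] <- TRUE
    keep
  }
  sel(br & fl > fm, fl, TRUE) & sel(br & t1 < tm, t1, FALSE)
}

#' Knowledge-based filtering mask
#'
#' The cross-intersection of the highest-valued `tail_fraction` of
#' supra-mode FLAIR voxels with the lowest-valued `tail_fraction` of
#' sub-mode T1-w voxels. With `scope = "per_slice"` the whole procedure
#' (modes, quantiles, intersection) runs independently on each slice.
#' An empty intersection is returned as a valid empty mask with a warning.
#'
#' @inheritParams mode_split
#' @return a [roi_mask].
#' @export
kbf_mask <- function(flair, t1, brain, params = kbf_params()) {
  if (!identical(dim(flair$grid), dim(t1$grid)) ||
      !identical(dim(flair$grid), dim(brain$grid)))
    stop("FLAIR, T1-w and brain mask shapes differ")
  f <- params$tail_fraction
  if (params$scope == "per_volume") {
    sel <- kbf_core(flair$grid, t1$grid, brain$grid, f, params$mode_bins)
  } else {
    sel <- array(FALSE, dim(flair$grid))
    for (k in seq_len(dim(flair$grid)[3]))
      sel[, , k] <- kbf_core(flair$grid[, , k, drop = FALSE],
                             t1$grid[, , k, drop = FALSE],
                             brain$grid[, , k, drop = FALSE],
                             f, params$mode_bins)
  }
  if (!any(sel))
    warning("KBF produced an empty ROI mask")
  roi_mask(sel)
}

#' Mask a volume by point-wise multiplication with an ROI
#'
#' @param flair a [brain_volume].
#' @param roi a [roi_mask] of the same shape.
#' @return a [brain_volume] equal to the elementwise product.
#' @export
apply_roi <- function(flair, roi) {
  if (!identical(dim(flair$grid), dim(roi$grid)))
    stop("volume and ROI shapes differ")
  out <- flair
  out$grid <- flair$grid * roi$grid
  out
}

#' Crop to a fixed cube around the brain and normalize to the unit range
#'
#' The `crop_side`-cube window is centered on the brain bounding-box center
#' and shifted minimally along each axis so that every ROI voxel stays
#' inside; where the volume is smaller than the window, zero padding fills
#' the remainder. Values are then min-max scaled to `[0, 1]` over the
#' window (a constant window becomes all zeros).
#'
#' @param masked_flair the ROI-masked FLAIR [brain_volume].
#' @param brain a [brain_mask].
#' @param roi a [roi_mask].
#' @param params a [kbf_params] (supplies `crop_side`).
#' @return a [brain_volume] of size `crop_side^3` with attribute `"window"`
#'   giving the 1-based start index of the window along each axis.
#' @export
crop_and_normalize <- function(masked_flair, brain, roi,
                               params = kbf_params()) {
  side <- params$crop_side
  d <- dim(masked_flair$grid)
  start <- integer(3)
  for (a in 1:3) {
    bidx <- range(which(apply(brain$grid, a, any)))
    s0 <- round(mean(bidx) - (side - 1) / 2)
    if (roi$n_voxels > 0L) {
      ridx <- range(which(apply(roi$grid, a, any)))
      if (diff(ridx) + 1L > side)
        stop(sprintf(
          "ROI extent along axis %d (%d voxels) exceeds crop side %d",
          a, diff(ridx) + 1L, side))
      s0 <- min(max(s0, ridx[2] - side + 1L), ridx[1])
    }
    start[a] <- s0
  }
  out <- masked_flair
  out$grid <- apply_crop_window(masked_flair$grid, start, side)
  r <- range(out$grid)
  out$grid <- if (diff(r) == 0) array(0, dim(out$grid))
              else (out$grid - r[1]) / diff(r)
  attr(out, "window") <- start
  out
}

#' Extract a cubic window from a 3D array with zero padding
#'
#' @param grid 3D array.
#' @param start 1-based window start per axis (may be outside the array).
#' @param side window side length.
#' @return `side^3` array.
#' @export
apply_crop_window <- function(grid, start, side) {
  d <- dim(grid)
  out <- array(0, rep(side, 3L))
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(start[a], 1L); hi <- min(start[a] + side - 1L, d[a])
    if (lo > hi) return(out)
    src[[a]] <- lo:hi
    dst[[a]] <- (lo - start[a] + 1L):(hi - start[a] + 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    grid[src[[1]], src[[2]], src[[3]]]
  out
}

#' Run the full KBF stage on prepared volumes
#'
#' Convenience wrapper: [kbf_mask], [apply_roi], [crop_and_normalize],
#' plus the ROI cropped through the same window (needed e.g. to pick the
#' slices fed to the 2D classifier).
#'
#' @inheritParams mode_split
#' @return list with elements `roi` ([roi_mask]), `input` (the cropped,
#'   normalized, ROI-masked FLAIR [brain_volume]), `roi_cropped` (binary
#'   array in window coordinates) and `window`.
#' @export
kbf_pipeline <- function(flair, t1, brain, params = kbf_params()) {
  roi <- kbf_mask(flair, t1, brain, params)
  masked <- apply_roi(flair, roi)
  input <- crop_and_normalize(masked, brain, roi, params)
  w <- attr(input, "window")
  list(roi = roi, input = input,
       roi_cropped = apply_crop_window(roi$grid * 1, w, params$crop_side),
       window = w)
}
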