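# Volume preparation: isotropic resampling, reorientation to the sagittal
# standard, brain masking with a simple intensity-based fallback.

# Sample `grid` at fractional 0-based voxel coordinates `pts` (N x 3) by
# trilinear interpolation; points outside the grid get `fill`.
trilinear_sample <- function(grid, pts, fill = NA_real_, clamp = FALSE) {
  d <- dim(grid)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  eps <- 1e-9
  inside <- clamp |
            (x >= -eps & x <= d[1] - 1 + eps &
             y >= -eps & y <= d[2] - 1 + eps &
             z >= -eps & z <= d[3] - 1 + eps)
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  x <- cl(x, d[1]); y <- cl(y, d[2]); z <- cl(z, d[3])
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  lin <- function(i, j, k) 1 + i + j * d[1] + k * d[1] * d[2]
  g <- grid
  val <-
    g[lin(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    g[lin(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
    g[lin(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
    g[lin(x1, y1, z0)] * fx       * fy       * (1 - fz) +
    g[lin(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    g[lin(x1, y0, z1)] * fx       * (1 - fy) * fz +
    g[lin(x0, y1, z1)] * (1 - fx) * fy       * fz +
    g[lin(x1, y1, z1)] * fx       * fy       * fz
  val[!inside] <- fill
  val
}

grid_coords <- function(out_dim, step = c(1, 1, 1), scale = c(1, 1, 1)) {
  ax <- lapply(1:3, function(a) (0:(out_dim[a] - 1)) * step[a] / scale[a])
  cbind(rep(ax[[1]], times = out_dim[2] * out_dim[3]),
        rep(rep(ax[[2]], each = out_dim[1]), times = out_dim[3]),
        rep(ax[[3]], each = out_dim[1] * out_dim[2]))
}

#' Resample a volume to 1 mm isotropic resolution
#'
#' Output size along each axis is `round((n - 1) * s) + 1` (voxel-center
#' extent convention) where `n` is the input size and `s` the input spacing
#' in mm. Intensities are interpolated trilinearly; use `"nearest"` for
#' masks. The operation is idempotent: a volume already at unit spacing is
#' returned with an identical grid.
#'
#' @param vol a [brain_volume].
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return a [brain_volume] with spacing `(1, 1, 1)` mm.
#' @export
resample_isotropic <- function(vol,
                               interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  validate_volume(vol)
  d <- dim(vol$grid); s <- vol$spacing
  out_dim <- round((d - 1) * s) + 1
  pts <- grid_coords(out_dim, scale = s)
  if (interpolation == "nearest") {
    pts <- round(pts)
    pts[, 1] <- pmin(pts[, 1], d[1] - 1)
    pts[, 2] <- pmin(pts[, 2], d[2] - 1)
    pts[, 3] <- pmin(pts[, 3], d[3] - 1)
    val <- vol$grid[1 + pts[, 1] + pts[, 2] * d[1] + pts[, 3] * d[1] * d[2]]
  } else {
    # edge-clamped: the rounded output extent may overhang the last voxel
    # center by a fraction of a voxel
    val <- trilinear_sample(vol$grid, pts, clamp = TRUE)
  }
  brain_volume(array(val, dim = out_dim), spacing = c(1, 1, 1),
               orientation = vol$orientation, modality = vol$modality,
               patient_id = vol$patient_id)
}

#' Reorient an axis-aligned volume to the sagittal standard
#'
#' Rounds each direction cosine to the nearest of -1, 0, 1; when the result
#' is a signed permutation the grid is permuted/flipped losslessly so that
#' the output orientation equals [sagittal_orientation()]. Applying the
#' operation to an already-sagittal volume is the identity.
#'
#' @param vol a [brain_volume] with (near) axis-aligned orientation.
#' @return a [brain_volume] in sagittal-standard orientation.
#' @export
reorient_to_sagittal <- function(vol) {
  validate_volume(vol)
  R <- round(vol$orientation)
  if (any(colSums(abs(R)) != 1) || any(rowSums(abs(R)) != 1))
    stop("degenerate orientation: direction cosines are not a signed ",
         "permutation after rounding")
  target <- sagittal_orientation()
  perm <- integer(3); flip <- logical(3)
  for (k in 1:3) {
    j <- which(abs(R[which(target[, k] != 0), ]) == 1)
    perm[k] <- j
    flip[k] <- sum(R[, j] * target[, k]) < 0
  }
  g <- aperm(vol$grid, perm)
  if (flip[1]) g <- g[dim(g)[1]:1, , , drop = FALSE]
  if (flip[2]) g <- g[, dim(g)[2]:1, , drop = FALSE]
  if (flip[3]) g <- g[, , dim(g)[3]:1, drop = FALSE]
  brain_volume(g, spacing = vol$spacing[perm], orientation = target,
               modality = vol$modality, patient_id = vol$patient_id)
}

#' Binary brain mask
#'
#' @param grid 3D array of 0/1 (or logical) values.
#' @param source `"external"` (e.g. from a dedicated skull-stripping tool)
#'   or `"fallback"` (produced by [fallback_brain_mask]).
#' @return object of class `brain_mask`.
#' @export
brain_mask <- function(grid, source = c("external", "fallback")) {
  source <- match.arg(source)
  if (!all(grid %in% c(0, 1))) stop("mask values must be 0/1")
  g <- array(grid != 0, dim = dim(grid))
  if (source == "external" && !any(g))
    stop("empty brain: external mask has no voxels")
  structure(list(grid = g, source = source), class = "brain_mask")
}

#' Zero out everything outside the brain
#'
#' @param vol a [brain_volume].
#' @param mask a [brain_mask] of the same shape.
#' @return the masked [brain_volume].
#' @export
apply_brain_mask <- function(vol, mask) {
  if (!identical(dim(vol$grid), dim(mask$grid)))
    stop("volume and mask shapes differ")
  if (!any(mask$grid)) stop("empty brain: mask selects no voxels")
  out <- vol
  out$grid[!mask$grid] <- 0
  out
}

# ---- simple morphology and components on 3D logical arrays ------------------

shift3 <- function(a, axis, by, fill) {
  d <- dim(a); out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  si <- list(TRUE, TRUE, TRUE); si[[axis]] <- src
  di <- list(TRUE, TRUE, TRUE); di[[axis]] <- src + by
  piece <- do.call(`[`, c(list(a), si, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), di, list(piece)))
}

box_dilate <- function(m) {
  for (ax in 1:3)
    m <- m | shift3(m, ax, 1L, FALSE) | shift3(m, ax, -1L, FALSE)
  m
}

box_erode <- function(m) {
  for (ax in 1:3)
    m <- m & shift3(m, ax, 1L, TRUE) & shift3(m, ax, -1L, TRUE)
  m
}

# 6-connected component labelling by iterative minimum-label propagation.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  repeat {
    m <- lab
    for (ax in 1:3) for (s in c(1L, -1L))
      m <- pmin(m, shift3(m, ax, s, Inf))
    m[!mask] <- Inf
    if (identical(m, lab)) break
    lab <- m
  }
  ids <- sort(unique(lab[is.finite(lab)]))
  out <- array(0L, d)
  out[mask] <- match(lab[mask], ids)
  out
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(mask)) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

otsu_threshold <- function(values, n_bins = 256L) {
  r <- range(values)
  if (diff(r) == 0) stop("near-constant volume")
  h <- tabulate(pmin(n_bins, 1L + floor((values - r[1]) / diff(r) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  r[1] + k / n_bins * diff(r)
}

#' Intensity-based fallback brain mask
#'
#' A stand-in used when no external skull-stripping mask is supplied:
#' voxels above a global two-class (Otsu) intensity threshold are taken as
#' foreground, the largest 6-connected component is kept, and the result is
#' closed with a 3x3x3 box to fill small gaps. The downstream ROI filter is
#' robust to the residual imprecision of such a mask.
#'
#' @param vol a [brain_volume].
#' @return a [brain_mask] with `source = "fallback"`.
#' @export
fallback_brain_mask <- function(vol) {
  validate_volume(vol)
  if (sd(vol$grid) < 1e-12) stop("near-constant volume")
  thr <- otsu_threshold(as.vector(vol$grid))
  fg <- vol$grid > thr
  if (!any(fg)) stop("near-constant volume")
  m <- box_erode(box_dilate(largest_component(fg)))
  if (!any(m)) m <- largest_component(fg)
  brain_mask(m * 1, source = "fallback")
}

# 7-point (face-neighbor) box smoothing, edge-replicated via shift fill.
box_smooth <- function(g) {
  acc <- g
  for (ax in 1:3) for (s in c(1L, -1L)) {
    sh <- shift3(g, ax, s, 0)
    # replicate the edge plane instead of zero-filling
    d <- dim(g); n <- d[ax]
    di <- list(TRUE, TRUE, TRUE)
    di[[ax]] <- if (s > 0) 1L else n
    sh <- do.call(`[<-`, c(list(sh), di,
                           list(do.call(`[`, c(list(g), di,
                                               list(drop = FALSE))))))
    acc <- acc + sh
  }
  acc / 7
}
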