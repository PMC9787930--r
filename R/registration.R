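# Inter-modality rigid registration: 6-DOF (three Euler angles, three
# translations) maximising normalised mutual information with a
# multi-resolution pattern search.

#' Rigid (6-DOF) transform
#'
#' Rotation is parameterised by Euler angles in degrees applied as
#' `Rz(rz) %*% Ry(ry) %*% Rx(rx)` about the volume center; translation is in
#' mm (equivalently voxels, since registration operates on isotropic
#' volumes). A point `x` in fixed-volume coordinates is mapped to the
#' moving-volume sampling coordinate `R (x - c) + c + t`.
#'
#' @param rotation numeric length-3 Euler angles in degrees, each in
#'   `(-180, 180]`.
#' @param translation numeric length-3 offsets in mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0),
                            translation = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  stopifnot(length(rotation) == 3L, length(translation) == 3L)
  if (any(rotation <= -180 | rotation > 180))
    stop("rotation angles must lie in (-180, 180] degrees")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation (deg): %.3f %.3f %.3f; ",
              x$rotation[1], x$rotation[2], x$rotation[3]))
  cat(sprintf("translation (mm): %.3f %.3f %.3f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

euler_angles <- function(R) {
  b <- -asin(max(-1, min(1, R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g) * 180 / pi
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform].
#' @return the inverse [rigid_transform]; composing the two is the identity.
#' @export
rigid_invert <- function(tf) {
  R <- rotation_matrix(tf$rotation)
  rigid_transform(rotation = euler_angles(t(R)),
                  translation = as.numeric(-t(R) %*% tf$translation))
}

#' Resample a volume through a rigid transform
#'
#' Pulls `moving` back onto the fixed grid: output voxel `x` takes the
#' trilinearly interpolated value of `moving` at `R (x - c) + c + t`, with
#' `c` the center of the output grid. Out-of-volume samples are 0.
#'
#' @param moving a [brain_volume] (isotropic).
#' @param tf a [rigid_transform].
#' @param out_dim output grid size (defaults to `dim(moving$grid)`).
#' @return a [brain_volume] on the fixed grid.
#' @export
apply_rigid <- function(moving, tf, out_dim = dim(moving$grid)) {
  pts <- grid_coords(out_dim)
  ctr <- (out_dim - 1) / 2
  R <- rotation_matrix(tf$rotation)
  pts_c <- sweep(pts, 2, ctr)
  mp <- pts_c %*% t(R)
  mp <- sweep(mp, 2, ctr + tf$translation, `+`)
  val <- trilinear_sample(moving$grid, mp, fill = 0)
  brain_volume(array(val, out_dim), spacing = moving$spacing,
               orientation = moving$orientation, modality = moving$modality,
               patient_id = moving$patient_id)
}

# Normalised mutual information (Studholme): (H(a) + H(b)) / H(a, b), from a
# `bins` x `bins` joint histogram over paired finite samples. The second
# (interpolated) image is binned with linear partial-volume weights so the
# similarity responds smoothly to sub-voxel transform changes.
nmi_similarity <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0L) stop("empty overlap between volumes")
  ra <- range(a)
  ia <- if (diff(ra) == 0) rep(1L, length(a))
        else pmin(bins, 1L + floor((a - ra[1]) / diff(ra) * bins))
  rb <- range(b)
  joint <- numeric(bins * bins)
  if (diff(rb) == 0) {
    acc <- rowsum(rep(1, length(a)), ia)
    joint[as.integer(rownames(acc))] <- acc
  } else {
    u <- (b - rb[1]) / diff(rb) * (bins - 1)   # 0 .. bins-1, continuous
    i0 <- pmin(floor(u), bins - 2)
    f <- u - i0
    idx <- c(ia + bins * i0, ia + bins * (i0 + 1L))
    acc <- rowsum(c(1 - f, f), idx)
    joint[as.integer(rownames(acc))] <- acc
  }
  p <- joint / sum(joint)
  ent <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  pj <- matrix(p, bins, bins)
  (ent(rowSums(pj)) + ent(colSums(pj))) / ent(p)
}

#' Rigid inter-modality registration
#'
#' Finds the 6-DOF transform maximising normalised mutual information
#' between `fixed` and the transformed `moving` volume, by greedy pattern
#' search over translations and Euler angles at a coarse-to-fine pyramid of
#' sampling grids. The reported similarity is non-decreasing across
#' refinement levels.
#'
#' @param moving,fixed isotropic [brain_volume]s in the same orientation.
#' @param levels integer downsampling factors, coarse to fine.
#' @param bins joint-histogram size for the similarity.
#' @param max_iter pattern-search iterations per level.
#' @return a [rigid_transform] `tf` such that `apply_rigid(moving, tf)`
#'   aligns with `fixed`; attribute `"similarity"` holds the per-level NMI.
#' @export
register_rigid <- function(moving, fixed, levels = c(4, 2, 1), bins = 32L,
                           max_iter = 60L) {
  validate_volume(moving); validate_volume(fixed)
  if (any(moving$spacing != 1) || any(fixed$spacing != 1))
    stop("volumes must be isotropically resampled before registration")
  # a light blur suppresses the interpolation-artifact maxima that
  # otherwise pin small rotations to zero at integer translations
  mov_grid <- box_smooth(moving$grid)
  fix_grid <- box_smooth(fixed$grid)
  d <- dim(fix_grid)
  ctr <- (d - 1) / 2
  levels <- levels[pmin(d[1], d[2], d[3]) / levels >= 8]
  if (length(levels) == 0L) levels <- 1
  par <- c(0, 0, 0, 0, 0, 0)  # (rx, ry, rz) deg, (tx, ty, tz) mm
  sims <- numeric(0)
  make_score <- function(f) {
    sub_dim <- pmax(2L, floor((d - 1) / f) + 1L)
    pts <- grid_coords(sub_dim, step = c(f, f, f))
    fvals <- trilinear_sample(fix_grid, pts, fill = NA_real_)
    function(p) {
      R <- rotation_matrix(p[1:3])
      mp <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + p[4:6], `+`)
      nmi_similarity(fvals, trilinear_sample(mov_grid, mp), bins = bins)
    }
  }
  fine_score <- make_score(min(levels))
  best_par <- par
  for (f in levels) {
    score <- if (f == min(levels)) fine_score else make_score(f)
    best <- score(par)
    r_step <- min(8, 2 * f); t_step <- 2 * f
    for (iter in seq_len(max_iter)) {
      improved <- FALSE
      for (j in 1:6) {
        step <- if (j <= 3) r_step else t_step
        for (sgn in c(1, -1)) {
          cand <- par; cand[j] <- cand[j] + sgn * step
          s <- score(cand)
          if (s > best + 1e-10) {
            par <- cand; best <- s; improved <- TRUE
          }
        }
      }
      if (!improved) {
        r_step <- r_step / 2; t_step <- t_step / 2
        if (r_step < 0.02 && t_step < 0.02) break
      }
    }
    # Similarity is reported on the finest sampling grid so levels are
    # comparable; a level that worsens the finest-grid alignment (possible,
    # since coarse levels optimise a coarser objective) is discarded.
    fs <- fine_score(par)
    if (length(sims) && fs < sims[length(sims)]) {
      par <- best_par; fs <- sims[length(sims)]
    }
    best_par <- par
    sims <- c(sims, fs)
  }
  out <- rigid_transform(rotation = par[1:3], translation = par[4:6])
  attr(out, "similarity") <- sims
  out
}
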