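#' Data-augmentation settings
#'
#' Classical augmentation for training: random in-plane rotations and axis
#' flips, each applied with a given probability.
#'
#' @param rotation_range maximum absolute rotation in degrees (rotation is
#'   drawn uniformly from `[-rotation_range, rotation_range]` in the plane
#'   of the first two axes). Free-angle rotations interpolate bilinearly,
#'   which low-pass filters fine texture; set `ortho_rotations` instead
#'   when texture must be preserved exactly.
#' @param flip_axes axes along which a flip may be applied.
#' @param probability probability in `[0, 1]` of applying each transform.
#' @param ortho_rotations if `TRUE`, draw a random rotation by a multiple
#'   of 90 degrees (grid-exact, no interpolation) instead of a free angle;
#'   for cubic 3D inputs the rotation plane is drawn at random from the
#'   three axis planes.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_range = 10, flip_axes = c(1L, 2L),
                                probability = 0.5,
                                ortho_rotations = FALSE) {
  if (probability < 0 || probability > 1)
    stop("probability must lie in [0, 1]")
  structure(list(rotation_range = rotation_range,
                 flip_axes = as.integer(flip_axes),
                 probability = probability,
                 ortho_rotations = isTRUE(ortho_rotations)),
            class = "augmentation_config")
}

# In-plane rotation (axes 1-2) by `theta` degrees about the array center,
# bilinear interpolation, shape-preserving; grid-exact at multiples of 90
# degrees.
rotate_inplane <- function(x, theta) {
  d <- dim(x)
  nd <- length(d)
  a <- theta * pi / 180
  c1 <- (d[1] - 1) / 2; c2 <- (d[2] - 1) / 2
  i <- rep(0:(d[1] - 1), times = d[2])
  j <- rep(0:(d[2] - 1), each = d[1])
  # pull-back: source coordinate of each output pixel
  si <- cos(a) * (i - c1) + sin(a) * (j - c2) + c1
  sj <- -sin(a) * (i - c1) + cos(a) * (j - c2) + c2
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  si <- snap(si); sj <- snap(sj)
  if (nd == 2L) {
    g3 <- array(x, dim = c(d, 1L))
    val <- trilinear_sample(g3, cbind(si, sj, 0), fill = 0)
    matrix(val, d[1], d[2])
  } else {
    out <- x
    n3 <- prod(d[-(1:2)])
    g <- array(x, dim = c(d[1], d[2], n3))
    for (k in seq_len(n3))
      out[, , k] <- matrix(
        trilinear_sample(array(g[, , k], c(d[1], d[2], 1L)),
                         cbind(si, sj, 0), fill = 0),
        d[1], d[2])
    out
  }
}

# Exact 90-degree rotation in the plane of axes `ax` (transpose + flip);
# no interpolation, so texture statistics are untouched.
rot90_plane <- function(x, ax, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    perm <- seq_along(dim(x)); perm[ax] <- ax[2:1]
    x <- flip_axis(aperm(x, perm), ax[1])
  }
  x
}

flip_axis <- function(x, axis) {
  d <- dim(x)
  idx <- rep(list(TRUE), length(d))
  idx[[axis]] <- d[axis]:1
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Randomly rotate and flip an input
#'
#' Applies, each with the configured probability, a random in-plane
#' rotation and flips along the configured axes. Output shape equals input
#' shape; with `probability = 0` the input is returned unchanged.
#'
#' @param x 2D or 3D numeric array.
#' @param cfg an [augmentation_config].
#' @param seed optional seed making the draw reproducible.
#' @return transformed array of the same shape.
#' @export
augment <- function(x, cfg = augmentation_config(), seed = NULL) {
  run <- function() {
    if (isTRUE(cfg$ortho_rotations) && cfg$probability > 0 &&
        runif(1) < cfg$probability) {
      planes <- if (length(dim(x)) == 3L && all(dim(x) == dim(x)[1]))
        list(c(1L, 2L), c(1L, 3L), c(2L, 3L)) else list(c(1L, 2L))
      x <- rot90_plane(x, planes[[sample(length(planes), 1)]],
                       k = sample(0:3, 1))
    } else if (cfg$probability > 0 && cfg$rotation_range > 0 &&
               runif(1) < cfg$probability) {
      x <- rotate_inplane(x, runif(1, -cfg$rotation_range,
                                   cfg$rotation_range))
    }
    for (ax in cfg$flip_axes) {
      if (ax <= length(dim(x)) && cfg$probability > 0 &&
          runif(1) < cfg$probability)
        x <- flip_axis(x, ax)
    }
    x
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
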