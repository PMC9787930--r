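# Attribution analyses on the trained classifier: integrated gradients and
# occlusion. Both attribute the logit (not the sigmoid) for gradient
# stability, with a zero baseline.

# Attribution works on a built/fitted classifier, or on any scalar-valued
# function supplied as list(value = function(x) ..., grad = function(x) ...)
# (grad only needed for integrated gradients).
as_xai_model <- function(model) {
  if (inherits(model, "mgmt_fit")) model <- model$model
  if (inherits(model, "mgmt_classifier")) {
    force(model)
    list(value = function(x) forward_logit(model, x),
         grad_batch = function(xs) input_gradients(model, xs))
  } else if (is.list(model) && is.function(model$value)) {
    g <- model$grad
    list(value = model$value,
         grad_batch = if (is.function(g)) function(xs) lapply(xs, g))
  } else {
    stop("need an mgmt_classifier, mgmt_fit, or list(value=, grad=)")
  }
}

attribution_map <- function(grid, method, baseline, extra = list()) {
  structure(c(list(grid = grid, method = method, baseline = baseline),
              extra),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> method %s, baseline %g, shape %s\n",
              x$method, x$baseline,
              paste(dim(x$grid), collapse = "x")))
  cat(sprintf("  attribution range [%.4g, %.4g]\n", min(x$grid),
              max(x$grid)))
  invisible(x)
}

# d(logit)/d(input) at a batch of inputs (evaluation mode).
input_gradients <- function(model, samples) {
  B <- length(samples)
  X <- nn_input_matrix(samples)
  fw <- nn_forward(model, X, B, training = FALSE, keep_cache = TRUE)
  bw <- nn_backward(model, fw$cache, rep(1, B), want_input_grad = TRUE)
  d <- dim(samples[[1]])
  lapply(seq_len(B), function(b) {
    v <- prod(d)
    array(bw$dX[(b - 1L) * v + seq_len(v), 1], dim = d)
  })
}

forward_logit <- function(model, x) {
  nn_forward(model, nn_input_matrix(list(x)), 1L, training = FALSE)$logit
}

#' Integrated-gradients attribution
#'
#' Attributes the classifier logit to each input voxel along the straight
#' path from a constant baseline to the input:
#' `attr_i = (x_i - b_i) * mean_s dF/dx_i` evaluated at
#' `b + (s/steps)(x - b)`, s = 1..steps (Riemann right sum). By the
#' completeness property the attributions sum to `F(x) - F(b)` up to the
#' discretisation error, which shrinks as `steps` grows.
#'
#' @param model an `mgmt_classifier` or `mgmt_fit`.
#' @param x input array matching the classifier input.
#' @param baseline scalar baseline value (default 0).
#' @param steps number of path points (>= 1).
#' @param chunk how many path points to evaluate per forward/backward batch.
#' @return an `attribution_map`; attributes `"F_x"` and `"F_baseline"` hold
#'   the logits at the endpoints.
#' @export
integrated_gradients <- function(model, x, baseline = 0, steps = 64L,
                                 chunk = 8L) {
  m <- as_xai_model(model)
  if (is.null(m$grad_batch))
    stop("integrated gradients needs a differentiable model")
  if (any(!is.finite(x))) stop("non-finite values in input")
  if (steps < 1) stop("steps must be >= 1")
  b <- array(baseline, dim(x))
  diffs <- x - b
  gsum <- array(0, dim(x))
  for (s0 in seq(1L, steps, by = chunk)) {
    ss <- s0:min(steps, s0 + chunk - 1L)
    pts <- lapply(ss, function(s) b + (s / steps) * diffs)
    gs <- m$grad_batch(pts)
    for (g in gs) gsum <- gsum + g
  }
  grid <- diffs * gsum / steps
  out <- attribution_map(grid, "integrated_gradients", baseline,
                         list(steps = as.integer(steps)))
  attr(out, "F_x") <- m$value(x)
  attr(out, "F_baseline") <- m$value(b)
  out
}

#' Occlusion attribution
#'
#' Slides a window over the input; each placement is replaced by the
#' baseline and the importance of the placement is the drop in the logit,
#' `F(x) - F(x_occluded)`. The per-voxel map averages the importances of
#' all windows covering the voxel. Window placements step by `stride` and
#' always include the final fitting position, so every voxel is covered.
#'
#' @param model an `mgmt_classifier` or `mgmt_fit`.
#' @param x input array.
#' @param window window side length (scalar, applied to every axis).
#' @param stride placement step (default `window / 2`).
#' @param baseline scalar replacement value (default 0).
#' @return an `attribution_map`.
#' @export
occlusion_map <- function(model, x, window = 16L, stride = max(1L, window %/% 2L),
                          baseline = 0) {
  m <- as_xai_model(model)
  d <- dim(x)
  window <- as.integer(window); stride <- as.integer(stride)
  if (any(window > d)) stop("occlusion window larger than the input")
  if (stride < 1) stop("stride must be >= 1")
  starts <- lapply(d, function(n)
    sort(unique(c(seq(1L, n - window + 1L, by = stride), n - window + 1L))))
  f_x <- m$value(x)
  ssum <- array(0, d); cnt <- array(0, d)
  place <- as.matrix(do.call(expand.grid, starts))
  nd <- length(d)
  for (r in seq_len(nrow(place))) {
    idx <- lapply(seq_len(nd), function(a)
      place[r, a]:(place[r, a] + window - 1L))
    xo <- x
    xo <- do.call(`[<-`, c(list(xo), idx, list(baseline)))
    imp <- f_x - m$value(xo)
    ssum <- do.call(`[<-`, c(list(ssum),
                             idx,
                             list(do.call(`[`, c(list(ssum), idx)) + imp)))
    cnt <- do.call(`[<-`, c(list(cnt), idx,
                            list(do.call(`[`, c(list(cnt), idx)) + 1)))
  }
  attribution_map(ssum / cnt, "occlusion", baseline,
                  list(window = window, stride = stride))
}

#' Pick the most informative slice of a 3D attribution map
#'
#' Selects the slice (third axis) with the largest total absolute
#' attribution; ties go to the lowest index.
#'
#' @param map an `attribution_map` over a 3D grid.
#' @return list with `slice_index`, the 2D `panel`, and the per-slice
#'   absolute sums (`slice_scores`), of class `attribution_slice`.
#' @export
summarize_slice <- function(map) {
  g <- map$grid
  if (length(dim(g)) != 3L) stop("summarize_slice needs a 3D map")
  scores <- apply(abs(g), 3, sum)
  i <- which.max(scores)
  structure(list(slice_index = i, panel = g[, , i], slice_scores = scores,
                 method = map$method),
            class = "attribution_slice")
}

#' @export
print.attribution_slice <- function(x, ...) {
  cat(sprintf("<attribution_slice> slice %d (%s), |attribution| = %.4g\n",
              x$slice_index, x$method, x$slice_scores[x$slice_index]))
  invisible(x)
}

#' @export
plot.attribution_slice <- function(x, ...) {
  graphics::image(x$panel, main = sprintf("%s, slice %d", x$method,
                                          x$slice_index),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}
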