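#' Architecture of the compact methylation classifier
#'
#' Declarative description of the sequential 2D/3D CNN: seven
#' depthwise-separable convolutional blocks followed by two fully connected
#' layers. Each block is a depthwise spatial convolution (kernel 3 per axis,
#' stride 2, padding 1, channel-preserving), a pointwise 1x1(x1) convolution
#' (stride 1, no padding) setting the output channels, batch normalization
#' and ReLU. The first block emits 8 channels and each later block doubles
#' them.
#'
#' @param dims 2 or 3: dimensionality of the convolutions (2D slices or 3D
#'   volumes).
#' @param input_side spatial side length of the (cubic/square) input; must
#'   be at least `2^(n_blocks - 1)` so the feature map does not collapse to
#'   a single voxel before the last block.
#' @param block_channels output channels of the seven blocks; after the
#'   first block each entry must double the previous one.
#' @param fc_hidden width of the first fully connected layer.
#' @param in_channels input channels (1: the masked FLAIR volume).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(dims = 3, input_side = 192,
                            block_channels = c(8, 16, 32, 64, 128, 256, 512),
                            fc_hidden = 64, in_channels = 1) {
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  n_blocks <- length(block_channels)
  if (n_blocks != 7L) stop("the classifier has seven convolutional blocks")
  if (any(block_channels[-1] != 2 * block_channels[-n_blocks]))
    stop("channels must double after the first block")
  if (input_side < 2^(n_blocks - 1))
    stop(sprintf(
      "input side %d too small to survive %d stride-2 blocks (need >= %d)",
      input_side, n_blocks, 2^(n_blocks - 1)))
  structure(list(dims = dims, input_side = as.integer(input_side),
                 block_channels = as.integer(block_channels),
                 spatial_kernel = 3L, spatial_stride = 2L,
                 spatial_padding = 1L, pointwise_kernel = 1L,
                 pointwise_stride = 1L, pointwise_padding = 0L,
                 fc_hidden = as.integer(fc_hidden),
                 in_channels = as.integer(in_channels), n_outputs = 1L),
            class = "classifier_spec")
}

#' Per-block spatial side lengths
#'
#' Applies the convolution size formula `floor((n + 2*pad - kernel)/stride)
#' + 1` through the seven blocks (with kernel 3, stride 2, pad 1 this is
#' `ceiling(n / 2)`).
#' @param spec a [classifier_spec].
#' @return integer vector of length 7.
#' @export
block_spatial_sizes <- function(spec) {
  n <- spec$input_side
  sizes <- integer(length(spec$block_channels))
  for (i in seq_along(sizes)) {
    n <- (n + 2L * spec$spatial_padding - spec$spatial_kernel) %/%
      spec$spatial_stride + 1L
    sizes[i] <- n
  }
  sizes
}

#' Build the methylation classifier
#'
#' Instantiates the network described by a [classifier_spec] with
#' He-initialised weights (convolutions carry no bias: batch normalization
#' follows immediately). The flattened last feature map feeds a hidden
#' fully connected layer (ReLU) and a final single-logit layer.
#'
#' @param spec a [classifier_spec].
#' @param init_seed seed for the weight initialisation.
#' @return object of class `mgmt_classifier`.
#' @export
build_classifier <- function(spec = classifier_spec(), init_seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  nb <- length(spec$block_channels)
  sizes <- block_spatial_sizes(spec)
  geom <- vector("list", nb)
  par <- list(); bn <- list()
  with_seed(init_seed, {
    side <- spec$input_side
    c_in <- spec$in_channels
    K <- spec$spatial_kernel^spec$dims
    for (i in seq_len(nb)) {
      geom[[i]] <- conv_index_map(rep(side, spec$dims))
      c_out <- spec$block_channels[i]
      par[[paste0("dw_", i)]] <-
        matrix(rnorm(K * c_in, sd = sqrt(2 / K)), K, c_in)
      par[[paste0("pw_", i)]] <-
        matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)
      par[[paste0("bn_gamma_", i)]] <- rep(1, c_out)
      par[[paste0("bn_beta_", i)]] <- rep(0, c_out)
      bn[[paste0("bn_mean_", i)]] <- rep(0, c_out)
      bn[[paste0("bn_var_", i)]] <- rep(1, c_out)
      side <- sizes[i]
      c_in <- c_out
    }
    flat <- sizes[nb]^spec$dims * spec$block_channels[nb]
    par$fc1_W <- matrix(rnorm(flat * spec$fc_hidden, sd = sqrt(2 / flat)),
                        flat, spec$fc_hidden)
    par$fc1_b <- rep(0, spec$fc_hidden)
    par$fc2_W <- matrix(rnorm(spec$fc_hidden, sd = sqrt(1 / spec$fc_hidden)),
                        spec$fc_hidden, 1)
    par$fc2_b <- 0
  })
  structure(list(spec = spec, par = par, bn = bn, geom = geom),
            class = "mgmt_classifier")
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar: depthwise and pointwise convolution
#' weights (no convolution biases), batch-norm scale/shift pairs and fully
#' connected weights and biases.
#' @param model an `mgmt_classifier` or `mgmt_fit`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "mgmt_fit")) model <- model$model
  stopifnot(inherits(model, "mgmt_classifier"))
  sum(vapply(model$par, length, numeric(1)))
}

#' Layer table of the classifier
#'
#' @param model an `mgmt_classifier`.
#' @return data.frame with one row per layer group.
#' @export
describe_classifier <- function(model) {
  if (inherits(model, "mgmt_fit")) model <- model$model
  spec <- model$spec
  sizes <- block_spatial_sizes(spec)
  nb <- length(spec$block_channels)
  c_in <- c(spec$in_channels, spec$block_channels[-nb])
  ks <- paste(rep(spec$spatial_kernel, spec$dims), collapse = "x")
  rows <- data.frame(
    layer = sprintf("block%d [dw %s s2 p1 + pw 1 + BN + ReLU]",
                    seq_len(nb), ks),
    out_channels = spec$block_channels,
    out_side = sizes,
    params = vapply(seq_len(nb), function(i)
      length(model$par[[paste0("dw_", i)]]) +
      length(model$par[[paste0("pw_", i)]]) +
      2L * spec$block_channels[i], numeric(1)))
  flat <- sizes[nb]^spec$dims * spec$block_channels[nb]
  rows <- rbind(rows,
    data.frame(layer = sprintf("fc1 [%d -> %d] + ReLU", flat,
                               spec$fc_hidden),
               out_channels = spec$fc_hidden, out_side = NA,
               params = flat * spec$fc_hidden + spec$fc_hidden),
    data.frame(layer = sprintf("fc2 [%d -> 1]", spec$fc_hidden),
               out_channels = 1, out_side = NA,
               params = spec$fc_hidden + 1))
  rows
}

#' @export
print.mgmt_classifier <- function(x, ...) {
  cat(sprintf("<mgmt_classifier> %dD, input side %d, %d trainable parameters\n",
              x$spec$dims, x$spec$input_side, count_parameters(x)))
  print(describe_classifier(x), row.names = FALSE)
  invisible(x)
}

#' Classify inputs with a built (or fitted) classifier
#'
#' @param object an `mgmt_classifier`.
#' @param newdata a single input array or a list of input arrays with side
#'   `spec$input_side` and `spec$dims` dimensions.
#' @param type `"prob"` (sigmoid probability of methylation) or `"logit"`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return numeric vector, one score per input.
#' @export
predict.mgmt_classifier <- function(object, newdata, type = c("prob", "logit"),
                                    batch_size = 8L, ...) {
  type <- match.arg(type)
  if (is.array(newdata) || is.matrix(newdata)) newdata <- list(newdata)
  expect_dim <- rep(object$spec$input_side, object$spec$dims)
  for (x in newdata) {
    if (!identical(as.integer(dim(x)), as.integer(expect_dim)))
      stop("input shape does not match the classifier's input side")
    if (any(!is.finite(x))) stop("non-finite values in classifier input")
  }
  n <- length(newdata)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    ix <- s:min(n, s + batch_size - 1L)
    X <- nn_input_matrix(newdata[ix])
    out[ix] <- nn_forward(object, X, length(ix), training = FALSE)$logit
  }
  if (type == "prob") 1 / (1 + exp(-out)) else out
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
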