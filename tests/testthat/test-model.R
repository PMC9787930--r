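test_that("the architecture spec enforces the seven-block doubling schema", {
  spec <- classifier_spec(dims = 3, input_side = 192)
  expect_length(spec$block_channels, 7L)
  expect_equal(spec$block_channels[1], 8L)
  expect_equal(spec$spatial_kernel, 3L)
  expect_equal(spec$spatial_stride, 2L)
  expect_equal(spec$spatial_padding, 1L)
  expect_equal(spec$pointwise_kernel, 1L)
  expect_error(classifier_spec(block_channels = c(8, 16, 32)), "seven")
  expect_error(classifier_spec(block_channels = c(8, 16, 32, 64, 100, 256, 512)),
               "double")
  expect_error(classifier_spec(dims = 3, input_side = 32), "too small")
  expect_error(classifier_spec(dims = 4), "dims")
})

test_that("per-block spatial sizes follow the convolution size formula", {
  spec <- classifier_spec(dims = 3, input_side = 192)
  expect_equal(block_spatial_sizes(spec), c(96L, 48L, 24L, 12L, 6L, 3L, 2L))
  # independent application of floor((n + 2p - k)/s) + 1
  n <- 192L
  for (s in block_spatial_sizes(spec)) {
    n <- (n + 2L - 3L) %/% 2L + 1L
    expect_equal(n, s)
  }
  expect_equal(block_spatial_sizes(classifier_spec(dims = 2, input_side = 64)),
               c(32L, 16L, 8L, 4L, 2L, 1L, 1L))
})

test_that("a built classifier has seven blocks, 8 first-block channels and a single logit", {
  model <- build_classifier(classifier_spec(dims = 2, input_side = 64), 1L)
  expect_length(model$geom, 7L)
  expect_equal(ncol(model$par$pw_1), 8L)
  tab <- describe_classifier(model)
  expect_equal(nrow(tab), 9L)  # 7 blocks + 2 fully connected layers
  x <- matrix(0, 64, 64)
  out <- predict(model, x, type = "logit")
  expect_length(out, 1L)
  expect_true(is.finite(out))
})

test_that("hand-counted parameters match: one 2D block 1 -> 8 costs 33 scalars", {
  model <- build_classifier(classifier_spec(dims = 2, input_side = 64), 1L)
  tab <- describe_classifier(model)
  expect_equal(tab$params[1], 9 + 8 + 16)  # depthwise 9, pointwise 8, BN 16
  # a fully connected layer in -> out with bias costs in*out + out
  fc2 <- tab$params[nrow(tab)]
  expect_equal(fc2, 64 * 1 + 1)
  expect_equal(count_parameters(model), sum(tab$params))
})

test_that("parameter counts stay below one million for both variants", {
  m3 <- build_classifier(classifier_spec(dims = 3, input_side = 192), 1L)
  m2 <- build_classifier(classifier_spec(dims = 2, input_side = 192), 1L)
  expect_lt(count_parameters(m3), 1e6)
  expect_lt(count_parameters(m2), 1e6)
})

test_that("evaluation-mode forward is deterministic with (batch, 1) output shape", {
  model <- build_classifier(classifier_spec(dims = 2, input_side = 64), 2L)
  set.seed(51)
  xs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64))
  p1 <- predict(model, xs)
  p2 <- predict(model, xs)
  expect_identical(p1, p2)
  expect_length(p1, 3L)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # zero-filled input gives a finite logit
  z <- predict(model, matrix(0, 64, 64), type = "logit")
  expect_true(is.finite(z))
  expect_error(predict(model, matrix(0, 32, 32)), "input side")
})

test_that("2D and 3D variants share the identical block schema", {
  s2 <- classifier_spec(dims = 2, input_side = 64)
  s3 <- classifier_spec(dims = 3, input_side = 64)
  expect_equal(s2$block_channels, s3$block_channels)
  expect_equal(s2[c("spatial_kernel", "spatial_stride", "spatial_padding",
                    "pointwise_kernel")],
               s3[c("spatial_kernel", "spatial_stride", "spatial_padding",
                    "pointwise_kernel")])
  m2 <- build_classifier(s2, 1L); m3 <- build_classifier(s3, 1L)
  expect_equal(nrow(m2$par$dw_1), 9L)   # 3x3 taps
  expect_equal(nrow(m3$par$dw_1), 27L)  # 3x3x3 taps
})

test_that("augmentation with probability 0 is the identity, flips are involutions", {
  set.seed(52)
  x <- array(runif(6 * 6 * 6), c(6, 6, 6))
  expect_identical(augment(x, augmentation_config(probability = 0)), x)
  f <- kbfmgmt:::flip_axis(kbfmgmt:::flip_axis(x, 2), 2)
  expect_identical(f, x)
  # seeded augmentation is reproducible
  cfg <- augmentation_config(rotation_range = 15, probability = 1)
  expect_identical(augment(x, cfg, seed = 9), augment(x, cfg, seed = 9))
})

test_that("a 90-degree rotation equals explicit index remapping", {
  m <- matrix(1:16, 4, 4)  # asymmetric
  got <- kbfmgmt:::rotate_inplane(m, 90)
  expect_equal(got, oracle_rot90(m))
  # and rotating back is the identity
  expect_equal(kbfmgmt:::rotate_inplane(got, -90), m)
  # 3D: the same in-plane map applies to every slice
  a <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  ra <- kbfmgmt:::rotate_inplane(a, 90)
  for (k in 1:3) expect_equal(ra[, , k], oracle_rot90(a[, , k]))
})
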