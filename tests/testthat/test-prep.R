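test_that("resampling obeys the voxel-center size formula and unit spacing", {
  set.seed(5)
  vol <- brain_volume(array(rnorm(64 * 64 * 32), c(64L, 64L, 32L)),
                      spacing = c(1, 1, 2))
  out <- resample_isotropic(vol)
  expect_equal(out$spacing, c(1, 1, 1))
  expect_identical(dim(out$grid), c(64L, 64L, 63L))
  # interpolation stays inside the input range
  expect_gte(min(out$grid), min(vol$grid))
  expect_lte(max(out$grid), max(vol$grid))
})

test_that("resampling is the identity at unit spacing and idempotent", {
  set.seed(6)
  vol <- brain_volume(array(rnorm(5 * 6 * 7), c(5L, 6L, 7L)))
  expect_equal(resample_isotropic(vol)$grid, vol$grid)
  aniso <- brain_volume(array(runif(20 * 15 * 10), c(20L, 15L, 10L)),
                        spacing = c(0.7, 1.3, 2.1))
  once <- resample_isotropic(aniso)
  twice <- resample_isotropic(once)
  expect_equal(twice$grid, once$grid, tolerance = 1e-6)
})

test_that("a constant volume resamples to the same constant", {
  vol <- brain_volume(array(7, c(9L, 9L, 5L)), spacing = c(1.5, 0.8, 2.2))
  out <- resample_isotropic(vol)
  expect_true(all(abs(out$grid - 7) < 1e-12))
})

test_that("sagittal reorientation is identity on sagittal input and invertible", {
  set.seed(7)
  vol <- brain_volume(array(rnorm(3 * 4 * 5), c(3L, 4L, 5L)))
  expect_equal(reorient_to_sagittal(vol)$grid, vol$grid)

  # an axial volume: rows along +x, columns along +y, slices along +z
  ax <- brain_volume(array(rnorm(3 * 4 * 5), c(3L, 4L, 5L)),
                     orientation = diag(3), modality = "FLAIR")
  sag <- reorient_to_sagittal(ax)
  expect_equal(sag$orientation, sagittal_orientation())
  expect_equal(sort(dim(sag$grid)), sort(dim(ax$grid)))
  # voxel-by-voxel oracle: a voxel at LPS position (x, y, z) must keep its
  # value; in the axial grid that position is index (x, y, z); in the
  # sagittal-standard grid it is (row=y, col=-z, slice=x)
  d <- dim(ax$grid)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    expect_identical(sag$grid[y, d[3] + 1 - z, x], ax$grid[x, y, z])
  }
})

test_that("degenerate direction cosines are rejected", {
  o <- matrix(c(1, 0, 0, sqrt(0.5), sqrt(0.5), 0, 0, 0, 1), 3, 3)
  vol <- brain_volume(array(0, c(2, 2, 2)), orientation = o)
  expect_error(reorient_to_sagittal(vol), "degenerate")
})

test_that("brain masking zeroes the outside and never adds voxels", {
  ph <- phantom_cache(seed = 3, label = 0)
  vol <- ph$flair
  all1 <- brain_mask(array(1, dim(vol$grid)), "external")
  expect_equal(apply_brain_mask(vol, all1)$grid, vol$grid)
  masked <- apply_brain_mask(vol, ph$brain_mask)
  expect_equal(sum(masked$grid != 0),
               sum(ph$brain_mask$grid & vol$grid != 0))
  expect_lte(sum(masked$grid != 0), sum(vol$grid != 0))
  # checkerboard on a constant volume zeroes exactly half
  cb <- array((rep(1:4, times = 16) + rep(rep(1:4, each = 4), times = 4) +
                 rep(1:4, each = 16)) %% 2, c(4L, 4L, 4L))
  cvol <- brain_volume(array(5, c(4L, 4L, 4L)))
  expect_equal(sum(apply_brain_mask(cvol, brain_mask(cb))$grid == 0), 32L)
  expect_error(apply_brain_mask(vol, brain_mask(array(0, dim(vol$grid)),
                                                "fallback")),
               "empty brain")
})

test_that("fallback brain mask recovers a known ellipsoid", {
  ph <- phantom_cache(seed = 11, label = 0)
  m <- fallback_brain_mask(ph$flair)
  expect_identical(m$source, "fallback")
  expect_gte(dice_coefficient(m$grid, ph$brain_mask$grid), 0.95)
})

test_that("fallback mask keeps only the largest blob and rejects flat input", {
  g <- array(0, c(24L, 24L, 24L))
  g[3:12, 3:12, 3:12] <- 100    # 1000 voxels
  g[18:20, 18:20, 18:20] <- 100 # 27 voxels
  m <- fallback_brain_mask(brain_volume(g))
  expect_true(all(!m$grid[17:21, 17:21, 17:21]))
  expect_true(any(m$grid[3:12, 3:12, 3:12]))
  expect_error(fallback_brain_mask(brain_volume(array(0, c(8, 8, 8)))),
               "near-constant")
})
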