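vol_of <- function(a) brain_volume(array(a, dim = dim(a)))

test_that("intensity mode tabulates exactly and breaks ties toward the smallest", {
  expect_equal(intensity_mode(c(1, 1, 2, 3)), 1)
  expect_equal(intensity_mode(c(5, 5, 7, 7)), 5)
  expect_equal(intensity_mode(c(-3, -3, 0, 4, 4)), -3)
  expect_error(intensity_mode(numeric(0)), "empty")
})

test_that("mode of a two-peak continuous mixture lands on the taller peak", {
  set.seed(31)
  v <- c(rnorm(6000, 100, 3), rnorm(4000, 60, 3))
  m <- intensity_mode(v, mode_bins = 100L)
  bin_width <- diff(range(v)) / 100
  expect_lt(abs(m - 100), 2 * bin_width)
  # brute-force histogram count agrees
  r <- range(v)
  idx <- pmin(100L, 1L + floor((v - r[1]) / diff(r) * 100))
  k <- which.max(tabulate(idx, nbins = 100L))
  expect_equal(m, r[1] + (k - 0.5) / 100 * diff(r))
})

test_that("mode split is strict and computed over in-brain voxels only", {
  d <- c(2L, 2L, 1L)
  br <- brain_mask(array(1, d))
  fl <- vol_of(array(c(1, 1, 2, 3), d))
  t1 <- vol_of(array(c(5, 5, 1, 2), d))
  ms <- mode_split(fl, t1, br)
  expect_equal(which(ms$supra_flair$grid), c(3L, 4L))  # values 2 and 3
  expect_equal(which(ms$sub_t1$grid), c(3L, 4L))       # values below mode 5
  # constant FLAIR: nothing is strictly above the mode
  msc <- mode_split(vol_of(array(7, d)), t1, br)
  expect_equal(msc$supra_flair$n_voxels, 0L)
  # T1 with everything >= mode: sub-mode set empty
  mst <- mode_split(fl, vol_of(array(c(4, 4, 5, 6), d)), br)
  expect_equal(mst$sub_t1$n_voxels, 0L)
  expect_error(mode_split(fl, vol_of(array(0, c(3, 3, 1))), br), "differ")
})

test_that("quantile selection keeps exactly ceiling(fraction * n) voxels", {
  set.seed(32)
  d <- c(10L, 10L, 10L)
  v <- vol_of(array(sample(1:1000), d))  # 1000 distinct values
  m <- roi_mask(array(TRUE, d))
  sel <- quantile_select(m, v, 0.25, "highest")
  expect_equal(sel$n_voxels, 250L)
  expect_setequal(which(sel$grid), which(v$grid > 750))  # full-sort oracle
  low <- quantile_select(m, v, 0.25, "lowest")
  expect_setequal(which(low$grid), which(v$grid <= 250))
  # ceiling rule: n = 10, fraction 0.25 -> k = 3
  m10 <- roi_mask(array(c(rep(TRUE, 10), rep(FALSE, 990)), d))
  expect_equal(quantile_select(m10, v, 0.25, "highest")$n_voxels, 3L)
  # empty mask passes through; bad fraction errors
  expect_equal(quantile_select(roi_mask(array(FALSE, d)), v, 0.25,
                               "highest")$n_voxels, 0L)
  expect_error(quantile_select(m, v, 0, "highest"), "fraction")
  expect_error(quantile_select(m, v, 1.2, "highest"), "fraction")
})

test_that("intensity ties at the cut resolve by voxel index, deterministically", {
  d <- c(4L, 4L, 1L)
  v <- vol_of(array(c(rep(5, 8), rep(9, 8)), d))
  m <- roi_mask(array(TRUE, d))
  sel <- quantile_select(m, v, 0.75, "highest")  # k = 12: all 9s + four 5s
  expect_equal(which(sel$grid), c(1:4, 9:16))
  sel2 <- quantile_select(m, v, 0.75, "highest")
  expect_identical(sel$grid, sel2$grid)
})

test_that("disjoint FLAIR-top and T1-low sets give an empty mask with a warning", {
  d <- c(4L, 4L, 2L)
  base <- rep(c(1, 10), each = 16)
  fl <- vol_of(array(base, d))           # top half bright in FLAIR
  t1 <- vol_of(array(base, d))           # same voxels bright in T1
  br <- brain_mask(array(1, d))
  expect_warning(m <- kbf_mask(fl, t1, br), "empty")
  expect_equal(m$n_voxels, 0L)
})

test_that("kbf_mask equals the brute-force sorted-list reference on random volumes", {
  set.seed(33)
  for (rep in 1:40) {
    cs <- random_kbf_case(12L)
    got <- suppressWarnings(
      kbf_mask(vol_of(cs$fl), vol_of(cs$t1), brain_mask(cs$br * 1),
               kbf_params()))
    want <- oracle_kbf(cs$fl, cs$t1, cs$br, 0.25)
    expect_identical(got$grid, want)
  }
})

test_that("per-slice scope runs the whole procedure independently per slice", {
  set.seed(34)
  cs <- random_kbf_case(10L)
  got <- suppressWarnings(
    kbf_mask(vol_of(cs$fl), vol_of(cs$t1), brain_mask(cs$br * 1),
             kbf_params(scope = "per_slice")))
  want <- array(FALSE, cs$d)
  for (k in seq_len(cs$d[3]))
    want[, , k] <- oracle_kbf(cs$fl[, , k, drop = FALSE],
                              cs$t1[, , k, drop = FALSE],
                              cs$br[, , k, drop = FALSE], 0.25)
  expect_identical(got$grid, want)
})

test_that("growing the tail fraction never drops a selected voxel; scaling changes nothing", {
  set.seed(35)
  cs <- random_kbf_case(12L)
  fl <- vol_of(cs$fl); t1 <- vol_of(cs$t1); br <- brain_mask(cs$br * 1)
  prev <- NULL
  for (f in c(0.1, 0.2, 0.3, 0.5)) {
    cur <- suppressWarnings(kbf_mask(fl, t1, br, kbf_params(tail_fraction = f)))
    expect_true(all(!cur$grid | br$grid))               # ROI within brain
    if (!is.null(prev)) expect_true(all(!prev | cur$grid))
    prev <- cur$grid
  }
  scaled <- suppressWarnings(
    kbf_mask(vol_of(cs$fl * 3), vol_of(cs$t1 * 3), br, kbf_params()))
  base <- suppressWarnings(kbf_mask(fl, t1, br, kbf_params()))
  expect_identical(scaled$grid, base$grid)
})

test_that("ROI multiplication masks point-wise", {
  set.seed(36)
  d <- c(6L, 5L, 4L)
  fl <- vol_of(array(sample(0:9, prod(d), TRUE), d))
  ones <- roi_mask(array(TRUE, d))
  expect_equal(apply_roi(fl, ones)$grid, fl$grid)
  none <- roi_mask(array(FALSE, d))
  expect_true(all(apply_roi(fl, none)$grid == 0))
  m <- roi_mask(array(runif(prod(d)) < 0.4, d))
  out <- apply_roi(fl, m)
  expect_identical(out$grid != 0, m$grid & fl$grid != 0)
  expect_error(apply_roi(fl, roi_mask(array(TRUE, c(2, 2, 2)))), "differ")
})

test_that("cropping produces the fixed cube, keeps the ROI, and normalizes to [0,1]", {
  ph <- phantom_cache(seed = 41, label = 1)
  kb <- suppressWarnings(
    kbf_pipeline(ph$flair, ph$t1, ph$brain_mask, kbf_params(crop_side = 192L)))
  expect_identical(dim(kb$input$grid), c(192L, 192L, 192L))
  expect_equal(min(kb$input$grid), 0)
  expect_equal(max(kb$input$grid), 1)
  # every ROI voxel survives the crop
  expect_equal(sum(kb$roi_cropped != 0), kb$roi$n_voxels)
  # small window: shifting must still keep all ROI voxels when they fit
  kb64 <- kbf_pipeline(ph$flair, ph$t1, ph$brain_mask,
                       kbf_params(crop_side = 64L))
  expect_equal(sum(kb64$roi_cropped != 0), kb64$roi$n_voxels)
  # constant window collapses to zeros
  zvol <- vol_of(array(0, c(8L, 8L, 8L)))
  out <- crop_and_normalize(zvol, brain_mask(array(1, c(8, 8, 8))),
                            roi_mask(array(FALSE, c(8, 8, 8))),
                            kbf_params(crop_side = 16L))
  expect_true(all(out$grid == 0))
})

test_that("an ROI wider than the crop side is refused with the overflow reported", {
  d <- c(30L, 8L, 8L)
  g <- array(FALSE, d); g[c(1, 30), 1, 1] <- TRUE
  expect_error(
    crop_and_normalize(vol_of(array(1, d)), brain_mask(array(1, d)),
                       roi_mask(g), kbf_params(crop_side = 16L)),
    "exceeds crop side")
})
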