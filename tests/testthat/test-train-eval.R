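test_that("fold assignment is stratified, disjoint, exhaustive and seeded", {
  pats <- data.frame(patient_id = sprintf("p%02d", 1:10),
                     label = c(rep(1, 6), rep(0, 4)))
  f <- make_folds(pats, k = 5, seed = 3)
  expect_equal(sort(unique(f$fold)), 1:5)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))      # 2 patients each
  pos_per_fold <- tapply(f$label, f$fold, sum)
  expect_true(all(pos_per_fold %in% c(1, 2)))
  # every patient in exactly one fold
  expect_equal(sort(f$patient_id), sort(pats$patient_id))
  # determinism
  expect_identical(make_folds(pats, k = 5, seed = 3)$fold, f$fold)
  expect_false(identical(make_folds(pats, k = 5, seed = 4)$fold, f$fold))
  # leave-one-out
  loo <- make_folds(pats, k = 10, seed = 1)
  expect_equal(sort(loo$fold), 1:10)
  expect_error(make_folds(pats, k = 11), "exceeds")
})

test_that("metric formulas match hand computation and handle edge cases", {
  # TP=3, FN=1, TN=2, FP=2
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.3, 0.1)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m <- evaluate_predictions(scores, labels)
  expect_equal(m$ACC, 0.625)
  expect_equal(m$SEN, 0.75)
  expect_equal(m$SPE, 0.5)
  expect_equal(m$PRE, 0.6)
  expect_equal(m$F1, 2 / 3)
  # perfect scores
  p <- evaluate_predictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  for (k in c("ACC", "SPE", "SEN", "PRE", "F1", "AUC"))
    expect_equal(p[[k]], 1)
  # constant scores: AUC 0.5 by tie credit
  expect_equal(evaluate_predictions(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$AUC,
               0.5)
  # undefined ratios are absent, not zero
  allneg <- evaluate_predictions(c(0.1, 0.2), c(0, 0))
  expect_true(is.na(allneg$SEN))
  expect_true(is.na(allneg$AUC))
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "nonempty")
  expect_error(evaluate_predictions(0.5, 2), "binary")
})

test_that("metrics agree with the brute-force confusion/rank oracle", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- rbinom(n, 1, 0.5)
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # force some ties
    m <- evaluate_predictions(scores, labels)
    o <- oracle_metrics(scores, labels)
    for (k in c("ACC", "SEN", "SPE", "PRE", "AUC", "TP", "TN", "FP", "FN"))
      expect_equal(m[[k]], o[[k]], info = k)
  }
})

test_that("a zero learning rate freezes the weights and the loss", {
  set.seed(62)
  xs <- lapply(1:6, function(i) matrix(runif(64 * 64), 64, 64))
  y <- rep(c(0, 1), 3)
  spec <- classifier_spec(dims = 2, input_side = 64)
  cfg <- train_config(max_epochs = 3, batch_size = 6, learning_rate = 0,
                      seed = 5,
                      augmentation = augmentation_config(probability = 0))
  fit <- train_fold(xs, y, spec, cfg)
  ref <- NULL
  kbfmgmt:::with_seed(5L, {
    ref <- build_classifier(spec,
                            init_seed = sample.int(.Machine$integer.max, 1))
  })
  expect_equal(fit$model$par, ref$par)
  expect_equal(diff(range(fit$history)), 0)
  expect_error(train_fold(xs, rep(1, 6), spec, cfg), "both classes")
})

test_that("one Adam step at positive learning rate reduces the training loss", {
  set.seed(63)
  xs <- lapply(1:8, function(i) matrix(runif(64 * 64) + 0.3 * (i %% 2), 64, 64))
  y <- rep(c(0, 1), 4)
  spec <- classifier_spec(dims = 2, input_side = 64)
  cfg <- train_config(max_epochs = 8, batch_size = 8, learning_rate = 5e-3,
                      seed = 6,
                      augmentation = augmentation_config(probability = 0))
  fit <- train_fold(xs, y, spec, cfg)
  expect_lt(fit$history[length(fit$history)], fit$history[1])
  # symmetry-view test-time averaging: same length, deterministic, in [0,1]
  p1 <- predict(fit, xs[1:2], tta = TRUE)
  p2 <- predict(fit, xs[1:2], tta = TRUE)
  expect_identical(p1, p2)
  expect_length(p1, 2L)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("cross-validation modes keep train and test patients disjoint", {
  set.seed(64)
  mk <- function(n, flip = FALSE, tag = "a") {
    y <- rep(c(0, 1), length.out = n)
    x <- lapply(seq_len(n), function(i) {
      base <- matrix(runif(64 * 64, 0, 0.3), 64, 64)
      sgn <- if (flip) 1 - y[i] else y[i]
      if (sgn == 1) base[1:20, 1:20] <- base[1:20, 1:20] + 1
      base
    })
    list(x = x, y = y, patient_id = sprintf("%s%02d", tag, seq_len(n)))
  }
  A <- mk(8, FALSE, "a"); B <- mk(8, TRUE, "b")
  spec <- classifier_spec(dims = 2, input_side = 64)
  cfg <- train_config(max_epochs = 4, batch_size = 4, seed = 11,
                      augmentation = augmentation_config(probability = 0))
  csv <- withr::local_tempfile(fileext = ".csv")
  cv <- run_cv(A, mode = "single", k = 2, spec = spec, config = cfg, seed = 2,
               out_csv = csv)
  expect_equal(nrow(cv$per_fold), 2L)
  expect_equal(nrow(cv$scores), 8L)  # every patient tested exactly once
  expect_equal(as.numeric(cv$mean[1, 1:6]),
               as.numeric(colMeans(cv$per_fold[, 2:7])), tolerance = 1e-12)
  tbl <- read.csv(csv)
  expect_equal(tbl$what, c("fold1", "fold2", "mean"))
  expect_equal(tbl$AUC[3], cv$mean$AUC)
  # merged mode: each merged test fold holds patients of both datasets
  cvm <- run_cv(A, mode = "merged", k = 2, spec = spec, config = cfg,
                data2 = B, seed = 2)
  for (f in 1:2) {
    te1 <- sum(cvm$folds$fold == f); te2 <- sum(cvm$folds2$fold == f)
    expect_gt(te1, 0); expect_gt(te2, 0)
    expect_equal(sum(cvm$scores$fold == f), te1 + te2)
  }
  expect_error(run_cv(A, mode = "cross", k = 2), "second dataset")
})

test_that("opposite-signal datasets: cross-dataset AUC collapses below within-dataset AUC", {
  set.seed(65)
  mk <- function(n, flip, tag) {
    y <- rep(c(0, 1), length.out = n)
    x <- lapply(seq_len(n), function(i) {
      base <- matrix(runif(64 * 64, 0, 0.3), 64, 64)
      sgn <- if (flip) 1 - y[i] else y[i]
      if (sgn == 1) base[10:40, 10:40] <- base[10:40, 10:40] + 1
      base
    })
    list(x = x, y = y, patient_id = sprintf("%s%02d", tag, seq_len(n)))
  }
  A <- mk(12, FALSE, "a"); B <- mk(12, TRUE, "b")
  spec <- classifier_spec(dims = 2, input_side = 64)
  cfg <- train_config(max_epochs = 6, batch_size = 4, learning_rate = 2e-3,
                      seed = 12,
                      augmentation = augmentation_config(probability = 0))
  sA <- run_cv(A, "single", k = 2, spec = spec, config = cfg, seed = 3)
  sB <- run_cv(B, "single", k = 2, spec = spec, config = cfg, seed = 3)
  xAB <- run_cv(A, "cross", k = 2, spec = spec, config = cfg, data2 = B,
                seed = 3)
  expect_lt(xAB$mean$AUC, sA$mean$AUC)
  expect_lt(xAB$mean$AUC, sB$mean$AUC)
})
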