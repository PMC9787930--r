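#' Training protocol settings
#'
#' Defaults follow the study protocol: Adam, learning rate 5e-4, batch
#' size 8, at most 150 epochs.
#'
#' @param max_epochs maximum number of training epochs (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0; 0 is allowed and freezes the
#'   weights, which is occasionally useful as a control).
#' @param seed seed controlling initialisation, shuffling and augmentation.
#' @param weight_decay decoupled L2 penalty applied to convolution and
#'   fully connected weights (not to batch-norm parameters or biases);
#'   0 disables it.
#' @param augmentation an [augmentation_config] (use
#'   `augmentation_config(probability = 0)` to disable).
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 150L, batch_size = 8L,
                         learning_rate = 5e-4, seed = 42L,
                         weight_decay = 0,
                         augmentation = augmentation_config()) {
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (weight_decay < 0) stop("weight_decay must be >= 0")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 weight_decay = weight_decay,
                 augmentation = augmentation),
            class = "train_config")
}

#' Stratified patient-level fold assignment
#'
#' Partitions patients into `k` disjoint folds, stratified by label: within
#' each class, shuffled patients are dealt round-robin, so per-fold class
#' counts differ by at most one.
#'
#' @param patients data.frame with columns `patient_id` and `label` (0/1).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return object of class `fold_split`: the input data.frame with an added
#'   `fold` column.
#' @export
make_folds <- function(patients, k = 5L, seed = 42L) {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "label") %in% names(patients)))
  n <- nrow(patients)
  if (k > n) stop("k exceeds the number of patients")
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id")
  fold <- integer(n)
  with_seed(seed, {
    # deal classes round-robin, continuing the rotation across classes so
    # total fold sizes stay balanced too
    start <- 0L
    for (lab in unique(patients$label)) {
      ix <- which(patients$label == lab)
      ix <- ix[sample.int(length(ix))]
      fold[ix] <- ((start + seq_along(ix) - 1L) %% k) + 1L
      start <- start + length(ix)
    }
  })
  out <- patients
  out$fold <- fold
  class(out) <- c("fold_split", "data.frame")
  attr(out, "k") <- as.integer(k)
  out
}

# Expand patient-level inputs to model-level samples. For the 3D variant a
# sample is the patient volume; for the 2D variant each patient contributes
# its list of slices, all carrying the patient label.
expand_samples <- function(x, y) {
  if (length(x) && is.list(x[[1]])) {
    patient <- rep(seq_along(x), lengths(x))
    list(samples = unlist(x, recursive = FALSE), y = y[patient],
         patient = patient)
  } else {
    list(samples = x, y = y, patient = seq_along(x))
  }
}

#' Fit the methylation classifier on a training set
#'
#' Trains with Adam and binary cross-entropy on the single logit for up to
#' `max_epochs` epochs, with seeded shuffling and augmentation. For the 2D
#' variant, pass each patient's input as a list of slices; every slice
#' carries the patient label.
#'
#' @param x list of input arrays (3D) or list of lists of slices (2D).
#' @param y binary labels (1 = methylation present), one per element of `x`.
#' @param spec a [classifier_spec].
#' @param config a [train_config].
#' @return object of class `mgmt_fit`: the trained model, the per-epoch
#'   loss `history`, and the configuration.
#' @export
train_fold <- function(x, y, spec = classifier_spec(),
                       config = train_config()) {
  if (length(x) == 0L || length(x) != length(y))
    stop("x and y must be nonempty and of equal length")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  ex <- expand_samples(x, y)
  n <- length(ex$samples)
  model <- NULL; state <- NULL; history <- numeric(0)
  with_seed(config$seed, {
    model <- build_classifier(spec,
                               init_seed = sample.int(.Machine$integer.max,
                                                      1))
    state <- list(t = 0L,
                   m = lapply(model$par, function(p) p * 0),
                   v = lapply(model$par, function(p) p * 0))
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0; n_batches <- 0L
      for (s in seq(1L, n, by = config$batch_size)) {
        ix <- ord[s:min(n, s + config$batch_size - 1L)]
        xs <- lapply(ex$samples[ix], augment, cfg = config$augmentation)
        X <- nn_input_matrix(xs)
        fw <- nn_forward(model, X, length(ix), training = TRUE,
                         keep_cache = TRUE)
        for (nm in names(fw$bn_updates)) model$bn[[nm]] <- fw$bn_updates[[nm]]
        lo <- nn_bce(fw$logit, ex$y[ix])
        bw <- nn_backward(model, fw$cache, lo$dlogit)
        upd <- nn_adam_step(model, bw$grads, state, config$learning_rate,
                            weight_decay = config$weight_decay)
        model <- upd$model; state <- upd$state
        epoch_loss <- epoch_loss + lo$loss; n_batches <- n_batches + 1L
      }
      history <- c(history, epoch_loss / n_batches)
    }
    
    
  })
  structure(list(model = model, history = history, config = config,
                 spec = spec, n_train = length(x)),
            class = "mgmt_fit")
}

#' @export
print.mgmt_fit <- function(x, ...) {
  cat(sprintf(
    "<mgmt_fit> %dD classifier, %d training patients, %d epochs\n",
    x$spec$dims, x$n_train, length(x$history)))
  cat(sprintf("  final training loss %.4f (initial %.4f)\n",
              x$history[length(x$history)], x$history[1]))
  cat(sprintf("  %d trainable parameters\n", count_parameters(x$model)))
  invisible(x)
}

#' @export
summary.mgmt_fit <- function(object, ...) {
  print(object)
  cat("\nArchitecture:\n")
  print(describe_classifier(object$model), row.names = FALSE)
  invisible(object)
}

#' @export
plot.mgmt_fit <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "Training history", ...)
  invisible(x)
}

#' Per-patient methylation scores from a fit
#'
#' For 3D inputs returns the sigmoid probability per patient; for 2D
#' patient inputs (lists of slices) returns the mean sigmoid output over
#' the patient's slices. With `tta = TRUE` each input is additionally
#' averaged over its grid-exact symmetry views (flips and 90-degree
#' in-plane rotations, 16 views), which stabilises borderline scores at
#' the cost of more forward passes.
#'
#' @param object an `mgmt_fit`.
#' @param newdata list of patient inputs as in [train_fold].
#' @param tta average predictions over symmetry views (default `FALSE`).
#' @param ... passed to `predict.mgmt_classifier`.
#' @return numeric vector of probabilities, one per patient.
#' @export
predict.mgmt_fit <- function(object, newdata, tta = FALSE, ...) {
  if (is.array(newdata) || is.matrix(newdata)) newdata <- list(newdata)
  ex <- expand_samples(newdata, rep(0, length(newdata)))
  samples <- ex$samples
  if (isTRUE(tta)) {
    views <- function(x) {
      out <- list()
      for (k in 0:3) {
        v <- rot90_plane(x, c(1L, 2L), k)
        out <- c(out, list(v, flip_axis(v, 1L)))
        if (length(dim(x)) == 3L)
          out <- c(out, list(flip_axis(v, 3L),
                             flip_axis(flip_axis(v, 1L), 3L)))
      }
      out
    }
    expanded <- lapply(samples, views)
    nv <- lengths(expanded)
    p <- predict(object$model, unlist(expanded, recursive = FALSE),
                 type = "prob", ...)
    p <- as.numeric(tapply(p, rep(seq_along(samples), nv), mean))
  } else {
    p <- predict(object$model, samples, type = "prob", ...)
  }
  as.numeric(tapply(p, ex$patient, mean))
}

#' Confusion-matrix and ranking metrics for binary scores
#'
#' Thresholds scores at `threshold` for the confusion matrix and computes
#' ACC, SPE, SEN, PRE, F1 and a rank-based (Mann-Whitney) AUC with half
#' credit for ties. Ratios with a zero denominator are reported as `NA`.
#' Positive class: methylation present.
#'
#' @param scores per-patient probabilities.
#' @param labels binary labels of equal length.
#' @param threshold classification threshold (default 0.5).
#' @return object of class `mgmt_metrics`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L || length(scores) != length(labels))
    stop("scores and labels must be nonempty and of equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  acc <- (tp + tn) / length(labels)
  sen <- ratio(tp, tp + fn)
  spe <- ratio(tn, tn + fp)
  pre <- ratio(tp, tp + fp)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_
        else 2 * pre * sen / (pre + sen)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  auc <- if (np == 0 || nn == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  }
  structure(list(ACC = acc, SPE = spe, SEN = sen, PRE = pre, F1 = f1,
                 AUC = auc, TP = tp, TN = tn, FP = fp, FN = fn),
            class = "mgmt_metrics")
}

#' @export
print.mgmt_metrics <- function(x, ...) {
  cat(sprintf(
    "ACC %.4f  SPE %.4f  SEN %.4f  PRE %.4f  F1 %.4f  AUC %.4f\n",
    x$ACC, x$SPE, x$SEN, x$PRE, x$F1, x$AUC))
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(ACC = m$ACC, SPE = m$SPE, SEN = m$SEN, PRE = m$PRE,
             F1 = m$F1, AUC = m$AUC, TP = m$TP, TN = m$TN, FP = m$FP,
             FN = m$FN)
}

#' k-fold cross-validation of the full classifier
#'
#' Three evaluation modes over labeled dataset(s):
#' * `single`: train and test within the folds of one dataset;
#' * `cross`: for each fold, train on the first dataset's training portion
#'   and test on the corresponding fold of the second dataset (whose fold
#'   structure is retained);
#' * `merged`: fold i of the merged experiment is the union of fold i of
#'   each dataset.
#'
#' Patients never appear in both the training and test side of a fold.
#'
#' @param data list with elements `x` (patient inputs as in [train_fold]),
#'   `y` (binary labels) and `patient_id`.
#' @param mode `"single"`, `"cross"` or `"merged"`.
#' @param k number of folds.
#' @param spec a [classifier_spec].
#' @param config a [train_config].
#' @param data2 second dataset (required for `cross` and `merged`).
#' @param seed fold-assignment seed.
#' @param out_csv optional path: per-fold and mean metrics written as CSV.
#' @return object of class `mgmt_cv`: `per_fold` data.frame, `mean` row,
#'   per-fold scores and fold assignments.
#' @export
run_cv <- function(data, mode = c("single", "cross", "merged"), k = 5L,
                   spec = classifier_spec(), config = train_config(),
                   data2 = NULL, seed = 42L, out_csv = NULL) {
  mode <- match.arg(mode)
  if (mode != "single" && is.null(data2))
    stop("modes 'cross' and 'merged' need a second dataset")
  f1 <- make_folds(data.frame(patient_id = data$patient_id, label = data$y),
                   k = k, seed = seed)
  f2 <- if (!is.null(data2))
    make_folds(data.frame(patient_id = data2$patient_id, label = data2$y),
               k = k, seed = seed + 1L)
  per_fold <- NULL
  scores <- vector("list", k)
  for (f in seq_len(k)) {
    if (mode == "single") {
      tr <- which(f1$fold != f); te <- which(f1$fold == f)
      xtr <- data$x[tr]; ytr <- data$y[tr]
      xte <- data$x[te]; yte <- data$y[te]
    } else if (mode == "cross") {
      tr <- which(f1$fold != f); te <- which(f2$fold == f)
      xtr <- data$x[tr]; ytr <- data$y[tr]
      xte <- data2$x[te]; yte <- data2$y[te]
    } else {
      tr1 <- which(f1$fold != f); tr2 <- which(f2$fold != f)
      te1 <- which(f1$fold == f); te2 <- which(f2$fold == f)
      xtr <- c(data$x[tr1], data2$x[tr2]); ytr <- c(data$y[tr1],
                                                    data2$y[tr2])
      xte <- c(data$x[te1], data2$x[te2]); yte <- c(data$y[te1],
                                                    data2$y[te2])
    }
    cfg <- config; cfg$seed <- config$seed + f
    fit <- train_fold(xtr, ytr, spec = spec, config = cfg)
    sc <- predict(fit, xte)
    scores[[f]] <- data.frame(fold = f, score = sc, label = yte)
    per_fold <- rbind(per_fold,
                      cbind(fold = f,
                            metrics_row(evaluate_predictions(sc, yte))))
  }
  mean_row <- as.data.frame(as.list(colMeans(per_fold[, -1])))
  out <- structure(list(mode = mode, k = k, per_fold = per_fold,
                        mean = mean_row, scores = do.call(rbind, scores),
                        folds = f1, folds2 = f2),
                   class = "mgmt_cv")
  if (!is.null(out_csv)) {
    tbl <- rbind(cbind(what = paste0("fold", per_fold$fold),
                       per_fold[, -1]),
                 cbind(what = "mean", mean_row))
    write.csv(tbl, out_csv, row.names = FALSE)
  }
  out
}

#' @export
print.mgmt_cv <- function(x, ...) {
  cat(sprintf("<mgmt_cv> mode '%s', %d folds\n", x$mode, x$k))
  print(x$per_fold[, 1:7], row.names = FALSE)
  cat("mean:\n")
  print(x$mean[, 1:6], row.names = FALSE)
  invisible(x)
}
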