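# Independent brute-force references used to validate the implementation.

# Reference KBF: materialises the sorted intensity lists and takes explicit
# set intersections. Intended for small integer-valued volumes, where the
# mode is an exact tabulation.
oracle_kbf <- function(fl, t1, br, fraction) {
  idx <- which(br)
  mode_of <- function(v) {
    tb <- table(v)
    as.numeric(names(tb)[which.max(tb)])
  }
  fm <- mode_of(fl[idx]); tm <- mode_of(t1[idx])
  hi <- idx[fl[idx] > fm]
  lo <- idx[t1[idx] < tm]
  take <- function(ii, v, decreasing) {
    if (length(ii) == 0L) return(integer(0))
    k <- ceiling(fraction * length(ii))
    o <- if (decreasing) order(-v[ii], ii) else order(v[ii], ii)
    ii[o][seq_len(k)]
  }
  sel <- intersect(take(hi, fl, TRUE), take(lo, t1, FALSE))
  m <- array(FALSE, dim(fl)); m[sel] <- TRUE
  m
}

# Reference metrics: explicit confusion counts and pairwise AUC with half
# credit for ties.
oracle_metrics <- function(scores, labels, thr = 0.5) {
  pred <- scores >= thr
  tp <- sum(pred & labels == 1); tn <- sum(!pred & labels == 0)
  fp <- sum(pred & labels == 0); fn <- sum(!pred & labels == 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  auc <- if (length(pos) == 0 || length(neg) == 0) NA_real_ else {
    tot <- 0
    for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
    tot / (length(pos) * length(neg))
  }
  list(ACC = (tp + tn) / length(labels),
       SEN = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       SPE = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       PRE = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       AUC = auc, TP = tp, TN = tn, FP = fp, FN = fn)
}

# Reference 90-degree in-plane rotation (counter-clockwise pull-back used by
# the augmenter), by explicit index remapping: out[i, j] = in[j, n+1-i].
oracle_rot90 <- function(m) {
  n <- nrow(m)
  out <- m
  for (i in seq_len(n)) for (j in seq_len(ncol(m)))
    out[i, j] <- m[j, n + 1 - i]
  out
}

# Small random integer-valued volume pair with a brain mask, for KBF
# equivalence checks.
random_kbf_case <- function(side_max = 16L) {
  d <- sample(4:side_max, 3, replace = TRUE)
  fl <- array(sample(0:25, prod(d), replace = TRUE), d)
  t1 <- array(sample(0:25, prod(d), replace = TRUE), d)
  br <- array(runif(prod(d)) < 0.7, d)
  if (!any(br)) br[1] <- TRUE
  list(fl = fl, t1 = t1, br = br, d = d)
}

phantom_cache <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, label = 0L, ...) {
    key <- paste0("s", seed, "_l", label, "_", paste(c(...), collapse = "_"))
    if (is.null(cache[[key]]))
      cache[[key]] <- make_phantom(phantom_params(...), seed = seed,
                                   label = label)
    cache[[key]]
  }
})

small_kbf_params <- function(...) kbf_params(crop_side = 64L, ...)
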