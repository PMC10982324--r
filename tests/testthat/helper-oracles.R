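# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately use naive loops, not the package's vectorized
# code paths.

# exhaustive Youden threshold: try every unique score as cutoff
brute_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  P <- sum(labels == 1); N <- sum(labels == 0)
  best_j <- -Inf; best_c <- NA_real_
  for (c0 in rev(cand)) {   # descending; ties resolved to smallest cutoff
    tpr <- sum(scores >= c0 & labels == 1) / P
    fpr <- sum(scores >= c0 & labels == 0) / N
    j <- tpr - fpr
    if (j >= best_j) { best_j <- j; best_c <- c0 }
  }
  list(threshold = best_c, j = best_j)
}

# pairwise win-count AUC
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# independent confusion tally
brute_confusion <- function(scores, labels, threshold) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1
    else if (pred && labels[i] == 0) fp <- fp + 1
    else if (!pred && labels[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# naive KNN imputation: per missing cell, enumerate donors by missing-aware
# distance and average the k nearest that observe the feature
brute_knn_impute <- function(values, k) {
  f <- ncol(values); n <- nrow(values)
  out <- values
  for (i in seq_len(n)) {
    for (j in seq_len(f)) {
      if (!is.na(values[i, j])) next
      d <- rep(Inf, n)
      for (t in seq_len(n)) {
        mutual <- !is.na(values[i, ]) & !is.na(values[t, ])
        if (any(mutual))
          d[t] <- f * mean((values[i, mutual] - values[t, mutual])^2) *
            sum(mutual) / sum(mutual)  # == f * mean sq diff
      }
      ord <- order(d)
      cand <- ord[!is.na(values[ord, j])]
      use <- cand[seq_len(min(k, length(cand)))]
      out[i, j] <- mean(values[use, j])
    }
  }
  out
}

# Mann-Whitney U (positive class) by direct pairwise counting
brute_u_stat <- function(xp, xn) {
  u <- 0
  for (a in xp) for (b in xn) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# minimal fitted-model stand-in for functions that only need weights/params
fake_wdd <- function(weights, prototype = rep(0, length(weights)),
                     variant = "knn", gamma = 1, delta = 1, lambda = 1,
                     threshold = 0.5) {
  f <- length(weights)
  fn <- names(weights) %||% sprintf("feat_%02d", seq_len(f))
  structure(list(variant = variant,
                 prototype = stats::setNames(prototype, fn),
                 weights = stats::setNames(weights, fn),
                 gamma = gamma, delta = delta, lambda = lambda,
                 threshold = threshold, f = f, feature_names = fn,
                 norm = NULL, norm2 = NULL,
                 control = wdd_control()), class = "wdd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small labeled cohort with controllable missingness
tiny_cohort <- function(n_per_class = 10, f = 5, shift = 1, missing = 0,
                        seed = 1) {
  planted_cohort(n_per_class, f, f, shift_sd = shift,
                 missing_rate = missing, seed = seed)
}
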