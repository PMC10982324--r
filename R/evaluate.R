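# Evaluation: confusion metrics, rank-based ROC AUC, stratified splitting,
# the repeated k-fold cross-validation protocol with a fixed independent
# test set, and age/sex subgroup modelling.

#' Confusion counts and threshold metrics
#'
#' Classifies by `score >= threshold -> positive` and computes accuracy,
#' precision, recall and F1. Precision and F1 are defined as 0 when no sample
#' is predicted positive (TP + FP = 0).
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels.
#' @param threshold Decision cutoff.
#' @return List with `tp`, `tn`, `fp`, `fn`, `acc`, `precision`, `recall`,
#'   `f1`.
#' @export
confusion_and_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       acc = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: `P(score_pos > score_neg) + 0.5 * P(tie)`, equal to
#' the trapezoidal area under the (FPR, TPR) curve over all cutoffs.
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stopf("roc_auc requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test holdout split
#'
#' Splits a cohort into a development set and an independent test set,
#' stratified by label, so the test set can be held fixed across repeated
#' cross-validation runs. The same seed always yields the same split.
#'
#' @param cohort A [wdd_cohort()].
#' @param test_fraction Fraction per class assigned to the test set.
#' @param seed Integer seed.
#' @return List with `dev` and `test` cohorts.
#' @export
holdout_split <- function(cohort, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    test_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      idx <- which(cohort$labels == cls)
      n_test <- round(length(idx) * test_fraction)
      if (n_test == 0 || n_test == length(idx))
        stopf("class %d too small (%d) for test_fraction %.2f",
              cls, length(idx), test_fraction)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
    list(dev = subset_cohort(cohort, setdiff(seq_along(cohort$labels),
                                             test_idx)),
         test = subset_cohort(cohort, test_idx))
  })
}

# stratified fold assignment: returns integer vector of fold ids
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    if (length(idx) < k)
      stopf("class %s has fewer samples (%d) than folds (%d)",
            cls, length(idx), k)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition the cohort is reshuffled (seeded) into `k` stratified
#' folds; per fold, preprocessing and the model are fitted on the training
#' folds only and metrics are computed on the held-out fold at the model's
#' Youden threshold. Fold metrics are averaged within a repetition; the
#' summary reports the mean and SD of each metric across repetitions.
#'
#' @param cohort A [wdd_cohort()] (the development set).
#' @param variant,gamma,delta,lambda,control,... Passed to [wdd()].
#' @param k Number of folds.
#' @param repetitions Number of seeded repetitions.
#' @param seed Base seed; repetition `r` uses `seed + r - 1`.
#' @return A `wdd_cv` object: list with `summary` (data frame metric /
#'   mean / sd), `per_repetition` (repetitions x metrics matrix), and the
#'   protocol parameters.
#' @export
repeated_cv <- function(cohort, variant = "di", gamma = 1, delta = 1,
                        lambda = 1, control = wdd_control(), k = 10,
                        repetitions = 10, seed = 1, ...) {
  metrics <- c("auc", "acc", "precision", "recall", "f1")
  per_rep <- matrix(NA_real_, repetitions, length(metrics),
                    dimnames = list(NULL, metrics))
  for (r in seq_len(repetitions)) {
    folds <- with_seed(seed + r - 1L, stratified_folds(cohort$labels, k))
    fold_m <- matrix(NA_real_, k, length(metrics))
    for (fi in seq_len(k)) {
      train <- subset_cohort(cohort, folds != fi)
      test <- subset_cohort(cohort, folds == fi)
      fit <- wdd(train, variant = variant, gamma = gamma, delta = delta,
                 lambda = lambda, control = control, ...)
      sc <- predict(fit, test)
      cm <- confusion_and_metrics(sc, test$labels, fit$threshold)
      fold_m[fi, ] <- c(roc_auc(sc, test$labels), cm$acc, cm$precision,
                        cm$recall, cm$f1)
    }
    per_rep[r, ] <- colMeans(fold_m)
  }
  summary <- data.frame(metric = metrics, mean = colMeans(per_rep),
                        sd = apply(per_rep, 2, stats::sd))
  if (repetitions == 1) summary$sd <- 0
  structure(list(summary = summary, per_repetition = per_rep,
                 variant = variant, k = k, repetitions = repetitions,
                 seed = seed),
            class = "wdd_cv")
}

#' @export
print.wdd_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repetitions, variant %s (seed %d)\n",
              x$k, x$repetitions, x$variant, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.4f (%.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Full screening evaluation protocol
#'
#' The benchmark protocol: a fixed stratified 8:2 development/independent-test
#' split, repeated stratified k-fold cross-validation on the development set
#' for each requested variant, plus a final model fitted on the full
#' development set and evaluated once on the independent test set (model
#' fitting is deterministic given the data, so repeating the independent test
#' would reproduce identical numbers).
#'
#' @param cohort A [wdd_cohort()].
#' @param variants Character vector among `"knn"`, `"di"`, `"bf"`.
#' @param test_fraction Independent test fraction.
#' @param k,repetitions CV protocol parameters.
#' @param seed Protocol seed (split and fold shuffles).
#' @param gamma,delta,lambda,control,... Passed to [wdd()].
#' @return A `wdd_protocol` object with elements `cv` (named list of
#'   [repeated_cv()] results), `independent` (named list of metric lists),
#'   `models` (final dev-fitted models) and `table` (a tidy summary data
#'   frame: variant x metric with CV mean/sd and independent-test value).
#' @export
screening_protocol <- function(cohort, variants = c("knn", "di", "bf"),
                               test_fraction = 0.2, k = 10, repetitions = 10,
                               seed = 1, gamma = 1, delta = 1, lambda = 1,
                               control = wdd_control(), ...) {
  sp <- holdout_split(cohort, test_fraction, seed = seed)
  cv <- list(); indep <- list(); models <- list()
  rows <- list()
  for (v in variants) {
    cv[[v]] <- repeated_cv(sp$dev, variant = v, gamma = gamma, delta = delta,
                           lambda = lambda, control = control, k = k,
                           repetitions = repetitions, seed = seed, ...)
    fit <- wdd(sp$dev, variant = v, gamma = gamma, delta = delta,
               lambda = lambda, control = control, ...)
    models[[v]] <- fit
    sc <- predict(fit, sp$test)
    cm <- confusion_and_metrics(sc, sp$test$labels, fit$threshold)
    indep[[v]] <- list(auc = roc_auc(sc, sp$test$labels), acc = cm$acc,
                       precision = cm$precision, recall = cm$recall,
                       f1 = cm$f1)
    s <- cv[[v]]$summary
    rows[[v]] <- data.frame(variant = v, metric = s$metric,
                            cv_mean = s$mean, cv_sd = s$sd,
                            independent = unlist(indep[[v]])[s$metric])
  }
  structure(list(cv = cv, independent = indep, models = models,
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 split = sp, seed = seed, k = k, repetitions = repetitions),
            class = "wdd_protocol")
}

#' @export
print.wdd_protocol <- function(x, ...) {
  cat(sprintf("Screening protocol: fixed %d/%d dev/test split, %d-fold CV x %d repetitions (seed %d)\n",
              length(x$split$dev$labels), length(x$split$test$labels),
              x$k, x$repetitions, x$seed))
  tab <- x$table
  for (v in unique(tab$variant)) {
    cat(sprintf("\n  variant %s\n", v))
    tv <- tab[tab$variant == v, ]
    for (i in seq_len(nrow(tv)))
      cat(sprintf("    %-9s CV %.4f (%.4f)   independent %.4f\n",
                  tv$metric[i], tv$cv_mean[i], tv$cv_sd[i],
                  tv$independent[i]))
  }
  invisible(x)
}

#' Build age/sex subgroup definitions
#'
#' @param cohort A [wdd_cohort()] with age and sex covariates.
#' @param n_age_bins Number of contiguous age bins spanning the observed age
#'   range (bins are `[low, high)`, last bin closed).
#' @param mode `"all"` (age bins + sexes + age x sex crosses), `"age"`,
#'   `"sex"`, or `"age_sex"`.
#' @return Named list of logical sample-selection vectors.
#' @export
group_spec <- function(cohort, n_age_bins = 8,
                       mode = c("all", "age", "sex", "age_sex")) {
  mode <- match.arg(mode)
  if (is.null(cohort$age) || is.null(cohort$sex))
    stopf("group modelling requires age and sex covariates")
  edges <- seq(min(cohort$age), max(cohort$age), length.out = n_age_bins + 1)
  bin <- findInterval(cohort$age, edges, rightmost.closed = TRUE)
  groups <- list()
  age_names <- sprintf("age_%02.0f-%02.0f", edges[-length(edges)], edges[-1])
  if (mode %in% c("all", "age"))
    for (b in seq_len(n_age_bins))
      groups[[age_names[b]]] <- bin == b
  if (mode %in% c("all", "sex"))
    for (sx in c("male", "female"))
      groups[[paste0("sex_", sx)]] <- cohort$sex == sx
  if (mode %in% c("all", "age_sex"))
    for (b in seq_len(n_age_bins))
      for (sx in c("male", "female"))
        groups[[paste(age_names[b], sx, sep = "_")]] <-
          bin == b & cohort$sex == sx
  groups
}

#' Fit WDD models per age/sex subgroup
#'
#' Divides the cohort into subgroups (by default 8 age bins + 2 sexes +
#' 8 x 2 age-by-sex crosses = 26 groups), fits a model per group, and
#' assembles the features-by-groups matrix of normalized feature weights
#' (each column sums to 1). Groups with a single class are skipped with a
#' warning.
#'
#' @param cohort A [wdd_cohort()] with age and sex.
#' @param variant,gamma,delta,lambda,control,... Passed to [wdd()].
#' @param n_age_bins,mode Passed to [group_spec()].
#' @param min_per_class Minimum samples per class for a group to be fitted.
#' @return A `wdd_groups` object: list with `models` (named list of fitted
#'   models), `weights` (features x groups matrix, columns summing to 1),
#'   `metrics` (in-sample AUC/ACC per group) and `sizes`.
#' @export
group_models <- function(cohort, variant = "di", n_age_bins = 8,
                         mode = "all", gamma = 1, delta = 1, lambda = 1,
                         control = wdd_control(), min_per_class = 5, ...) {
  groups <- group_spec(cohort, n_age_bins, mode)
  models <- list(); metrics <- list(); sizes <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    labs <- cohort$labels[sel]
    if (sum(labs == 1L) < min_per_class || sum(labs == 0L) < min_per_class) {
      warning(sprintf("group '%s' skipped: needs >= %d samples per class (has %d/%d)",
                      g, min_per_class, sum(labs == 1L), sum(labs == 0L)),
              call. = FALSE)
      next
    }
    sub <- subset_cohort(cohort, sel)
    fit <- wdd(sub, variant = variant, gamma = gamma, delta = delta,
               lambda = lambda, control = control, ...)
    models[[g]] <- fit
    cm <- confusion_and_metrics(fit$train_scores, fit$train_labels,
                                fit$threshold)
    metrics[[g]] <- data.frame(group = g, n = length(labs),
                               auc = roc_auc(fit$train_scores,
                                             fit$train_labels),
                               acc = cm$acc)
    sizes[[g]] <- c(pos = sum(labs == 1L), neg = sum(labs == 0L))
  }
  if (!length(models)) stopf("no group retained both classes")
  feats <- cohort$feature_names
  weights <- sapply(models, function(m) {
    w <- numeric(length(feats)); names(w) <- feats
    w[names(m$weights)] <- m$weights / sum(m$weights)
    w
  })
  structure(list(models = models, weights = weights,
                 metrics = do.call(rbind, c(metrics,
                                            make.row.names = FALSE)),
                 sizes = sizes, mode = mode, n_age_bins = n_age_bins),
            class = "wdd_groups")
}

#' @export
print.wdd_groups <- function(x, ...) {
  cat(sprintf("WDD subgroup models: %d groups (mode '%s', %d age bins)\n",
              length(x$models), x$mode, x$n_age_bins))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
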