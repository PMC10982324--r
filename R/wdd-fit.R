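# The user-facing model fit: wdd() generic, preprocessing pipeline,
# optimizer dispatch, threshold selection.

#' Fit a weighted diversity density (WDD) screening model
#'
#' Learns a prototype point `x` and nonnegative per-feature weights `s` that
#' maximize the diversity density of the positive class while minimizing that
#' of the negative class, by full-batch first-order minimization of the
#' negative log-likelihood. Three variants are available:
#'
#' * `"knn"` — missing values are KNN-imputed before fitting; probabilities
#'   `exp(-gamma * Dist)` with `Dist = sum_k s_k (b_k - x_k)^2`.
#' * `"di"` — missing-value tolerant; the distance of a sample with `f_miss`
#'   missing features is divided by `(f - f_miss)^delta`, shrinking the
#'   diversity density of low-quality samples.
#' * `"bf"` — missing-value tolerant; a bounded per-feature similarity
#'   `exp(-gamma * s_k |b_k - x_k|)` is summed over observed features
#'   (each term raised to `lambda`), so missing features are simply ignored.
#'
#' Unless `preprocess = FALSE`, features are robustly normalized first
#' (out-of-fence values nulled, then centred/scaled; see
#' [fit_robust_stats()]), constant features dropped, and — for the
#' missing-value-tolerant variants — per-feature class missingness equalized.
#' The decision threshold is the Youden-optimal cutoff on the training risk
#' scores. Fitting is deterministic given the data and configuration.
#'
#' @param x A [wdd_cohort()], a formula (`label ~ .`), or a numeric matrix.
#' @param ... Passed on to methods.
#' @return An object of class `wdd`; see Details.
#' @seealso [predict.wdd()], [risk_report()], [weight_report()],
#'   [repeated_cv()]
#' @export
#' @examples
#' coh <- planted_cohort(150, 10, 3, shift_sd = 2, seed = 1)
#' fit <- wdd(coh, variant = "di", control = wdd_control(epochs = 150))
#' fit
#' head(predict(fit, coh))
wdd <- function(x, ...) UseMethod("wdd")

#' @rdname wdd
#' @param data A data frame holding the model variables (formula method).
#' @export
wdd.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  values <- as.matrix(mf[, -1, drop = FALSE])
  cl <- match.call()
  out <- wdd.default(values, y, ...)
  out$call <- cl
  out
}

#' @rdname wdd
#' @param y Binary 0/1 labels (default method).
#' @export
wdd.default <- function(x, y, ...) {
  out <- wdd.wdd_cohort(wdd_cohort(as.matrix(x), y), ...)
  out$call <- match.call()
  out
}

#' @rdname wdd
#' @param variant One of `"di"`, `"knn"`, `"bf"`.
#' @param gamma,delta,lambda Positive hyperparameters: `gamma` scales all
#'   distances, `delta` the DI division penalty, `lambda` the BF per-term
#'   exponent.
#' @param control A [wdd_control()] list.
#' @param preprocess Fit and apply robust normalization inside the model
#'   (recommended); the fitted statistics are stored for prediction.
#' @param equalize Equalize per-feature class missingness before fitting
#'   (default: yes for the missing-value-tolerant variants).
#' @param keep_data Keep the processed training matrix in the model (needed
#'   for prediction-time imputation with the `"knn"` variant).
#' @export
wdd.wdd_cohort <- function(x, variant = c("di", "knn", "bf"),
                           gamma = 1, delta = 1, lambda = 1,
                           control = wdd_control(), preprocess = TRUE,
                           equalize = NULL, keep_data = TRUE, ...) {
  variant <- match.arg(variant)
  stopifnot(gamma > 0, delta > 0, lambda > 0)
  cohort <- x
  if (!any(cohort$labels == 1L) || !any(cohort$labels == 0L))
    stopf("wdd() requires both classes in the training cohort")
  equalize <- equalize %||% (variant != "knn")

  norm <- NULL; norm2 <- NULL; impute_ref <- NULL
  coh <- cohort
  if (preprocess) {
    norm <- fit_robust_stats(cohort)
    coh <- apply_normalization(cohort, norm)
  }
  if (variant == "knn") {
    if (anyNA(coh$values)) {
      imp <- knn_impute(coh, k = control$impute_k, renormalize = FALSE)
      impute_ref <- imp$values
      if (preprocess) {
        norm2 <- fit_robust_stats(imp)
        coh <- apply_normalization(imp, norm2, null_outliers = FALSE)
      } else {
        coh <- imp
      }
    }
  } else if (equalize) {
    coh <- equalize_class_missingness(coh, seed = control$seed)
  }
  if (variant == "di" && any(rowSums(!is.na(coh$values)) == 0))
    stopf("DI variant: sample(s) with all features missing after preprocessing")

  f <- ncol(coh$values)
  x0 <- if (control$init_x == "pos_mean") {
    xm <- colMeans(coh$values[coh$labels == 1L, , drop = FALSE], na.rm = TRUE)
    xm[!is.finite(xm)] <- 0
    xm
  } else numeric(f)
  theta0 <- c(x0, rep(softplus_inv(control$init_s), f))

  fitter <- if (control$optimizer == "adam") adam_fit else sgd_fit
  opt <- fitter(coh$values, coh$labels, theta0, variant, gamma, delta,
                lambda, control)
  prototype <- opt$theta[seq_len(f)]
  weights <- softplus(opt$theta[f + seq_len(f)])
  names(prototype) <- names(weights) <- coh$feature_names

  model <- structure(list(
    variant = variant, prototype = prototype, weights = weights,
    raw_weights = opt$theta[f + seq_len(f)],
    gamma = gamma, delta = delta, lambda = lambda,
    threshold = NA_real_, f = f,
    feature_names = coh$feature_names,
    norm = norm, norm2 = norm2,
    loss = opt$loss, loss_history = opt$history,
    epochs_run = opt$epochs_run,
    control = control, equalized = equalize && variant != "knn",
    call = match.call()), class = "wdd")
  if (keep_data) {
    model$impute_reference <- impute_ref
    model$train_values <- coh$values
  }
  sc <- wdd_score_matrix(model, coh$values)
  model$train_scores <- sc$score
  model$train_labels <- coh$labels
  model$threshold <- youden_threshold(sc$score, coh$labels)
  model
}

# Score an already-preprocessed (model-space) matrix. Returns score, the
# per-feature decomposition distk (sums exactly to the aggregate), and f_miss.
wdd_score_matrix <- function(model, values) {
  values <- rbind(values)
  if (ncol(values) != model$f)
    stopf("expected %d features, got %d", model$f, ncol(values))
  if (model$variant %in% c("knn", "di")) {
    ws <- weighted_sq_dist(values, model$prototype, model$weights)
    d <- sweep(values, 2, model$prototype, `-`)
    d[is.na(d)] <- 0
    distk <- sweep(d * d, 2, model$weights, `*`)
    if (model$variant == "knn") {
      score <- exp(-model$gamma * ws$dist)
    } else {
      if (any(ws$f_miss >= model$f))
        stopf("DI variant: sample with all %d features missing has no defined score",
              model$f)
      score <- exp(-model$gamma * ws$dist / (model$f - ws$f_miss)^model$delta)
    }
    list(score = score, dist = ws$dist, f_miss = ws$f_miss, distk = distk)
  } else {
    bs <- bf_similarity(values, model$prototype, model$weights,
                        gamma = model$gamma, lam = model$lambda)
    list(score = bs$sim, dist = bs$sim,
         f_miss = as.integer(rowSums(is.na(values))), distk = bs$terms)
  }
}

# Map raw prediction input into the model's normalized feature space.
wdd_prepare_newdata <- function(model, newdata) {
  values <- if (inherits(newdata, "wdd_cohort")) newdata$values
  else as.matrix(as.data.frame(newdata)[,
         setdiff(colnames(as.data.frame(newdata)), c("label", "age", "sex")),
         drop = FALSE])
  storage.mode(values) <- "double"
  if (!is.null(model$norm)) {
    input_feats <- model$norm$feature
    if (is.null(colnames(values))) {
      if (ncol(values) != length(input_feats))
        stopf("newdata has %d features; model was fitted on %d",
              ncol(values), length(input_feats))
      colnames(values) <- input_feats
    }
    missing_cols <- setdiff(input_feats, colnames(values))
    if (length(missing_cols))
      stopf("newdata lacks feature(s): %s", paste(missing_cols, collapse = ", "))
    values <- values[, input_feats, drop = FALSE]
    values <- normalize_matrix(values, model$norm, null_outliers = TRUE)
  } else if (ncol(values) != model$f) {
    stopf("newdata has %d features; model expects %d", ncol(values), model$f)
  }
  if (model$variant == "knn" && anyNA(values)) {
    if (is.null(model$impute_reference))
      stopf(paste("KNN-variant model has no imputation reference stored;",
                  "impute newdata before prediction"))
    values <- impute_against(values, model$impute_reference,
                             model$control$impute_k)
    if (!is.null(model$norm2))
      values <- normalize_matrix(values, model$norm2, null_outliers = FALSE)
  } else if (model$variant == "knn" && !is.null(model$norm2)) {
    values <- normalize_matrix(values, model$norm2, null_outliers = FALSE)
  }
  values
}

# matrix-level normalization used by apply_normalization and prediction
normalize_matrix <- function(values, stats, null_outliers = TRUE) {
  keep <- which(stats$kept)
  values <- values[, keep, drop = FALSE]
  st <- stats[keep, ]
  if (null_outliers) {
    bad <- !is.na(values) &
      (sweep(values, 2, st$lower_fence, `<`) |
         sweep(values, 2, st$upper_fence, `>`))
    values[bad] <- NA_real_
  }
  sweep(sweep(values, 2, st$mu, `-`), 2, st$sigma, `/`)
}

#' Predict from a fitted WDD model
#'
#' @param object A fitted [wdd()] model.
#' @param newdata A [wdd_cohort()], matrix or data frame. Raw (unnormalized)
#'   values are expected when the model was fitted with `preprocess = TRUE`.
#' @param type `"score"` (risk score: `exp(-gamma * Dist)` in `(0, 1]` for
#'   the KNN/DI variants, the raw bounded similarity for BF), `"class"`
#'   (0/1 at the model threshold, rule `score >= threshold`), `"prob"`
#'   (positive-class membership probability) or `"report"` (a
#'   [risk_report()]).
#' @param ... Unused.
#' @return Numeric vector, integer vector, or `wdd_risk` object.
#' @export
predict.wdd <- function(object, newdata,
                        type = c("score", "class", "prob", "report"), ...) {
  type <- match.arg(type)
  values <- wdd_prepare_newdata(object, newdata)
  sc <- wdd_score_matrix(object, values)
  switch(type,
    score = sc$score,
    class = as.integer(sc$score >= object$threshold),
    prob = if (object$variant == "bf") bf_probs(sc$score)$pr_pos else
      sc$score,
    report = {
      rep <- list(score = sc$score, dist = sc$dist, f_miss = sc$f_miss,
                  distk = sc$distk,
                  predicted = as.integer(sc$score >= object$threshold),
                  variant = object$variant,
                  feature_names = object$feature_names,
                  threshold = object$threshold)
      class(rep) <- "wdd_risk"
      rep
    })
}

#' Per-sample risk report with per-feature contributions
#'
#' Scores every sample of a cohort and decomposes each score's underlying
#' aggregate into per-feature contributions `dist_k` (`s_k (b_k - x_k)^2` for
#' the KNN/DI variants, the bounded per-feature similarity term for BF).
#' `rowSums(distk)` reconstructs the aggregate exactly; missing features
#' contribute 0.
#'
#' @param model A fitted [wdd()] model.
#' @param cohort A [wdd_cohort()], matrix or data frame.
#' @return A `wdd_risk` object: list with `score`, `dist`, `f_miss`, `distk`
#'   (n x f matrix), `predicted`.
#' @export
risk_report <- function(model, cohort) {
  predict(model, cohort, type = "report")
}

#' @export
print.wdd_risk <- function(x, ...) {
  cat(sprintf("<wdd_risk> %d samples, variant %s, threshold %.4g\n",
              length(x$score), x$variant, x$threshold))
  cat(sprintf("  score range: [%.4g, %.4g]; predicted positives: %d\n",
              min(x$score), max(x$score), sum(x$predicted)))
  invisible(x)
}

#' Youden-optimal decision threshold
#'
#' Scans all unique observed scores as candidate cutoffs under the rule
#' `score >= cutoff -> positive` and returns the cutoff maximizing Youden's
#' J = TPR - FPR. Ties are broken toward the smallest qualifying cutoff
#' (maximal sensitivity at equal J).
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels.
#' @return The selected cutoff.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0) stopf("youden_threshold requires both classes")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cum_tp <- cumsum(l == 1L)
  # candidate cutoffs are unique scores; at cutoff s[i] (last of its ties),
  # everything with score >= s[i] is positive.
  last <- which(diff(s) != 0)
  last <- c(last, length(s))
  tp <- cum_tp[last]
  fp <- last - tp
  j <- tp / P - fp / N
  best <- max(j)
  cand <- s[last[j == best]]
  min(cand)
}

#' @export
print.wdd <- function(x, ...) {
  vn <- c(knn = "WDD-KNN (imputation)", di = "MVT-WDD-DI (division penalty)",
          bf = "MVT-WDD-BF (bounded similarity)")
  cat(sprintf("Weighted diversity density model: %s\n", vn[x$variant]))
  cat(sprintf("  %d features; gamma = %g", x$f, x$gamma))
  if (x$variant == "di") cat(sprintf(", delta = %g", x$delta))
  if (x$variant == "bf") cat(sprintf(", lambda = %g", x$lambda))
  cat("\n")
  cat(sprintf("  final loss %.4f after %d epochs; threshold %.4g\n",
              x$loss, x$epochs_run, x$threshold))
  w <- sort(x$weights / sum(x$weights), decreasing = TRUE)
  top <- utils::head(w, 5)
  cat("  top features by normalized weight:\n")
  for (nm in names(top)) cat(sprintf("    %-10s %.3f\n", nm, top[[nm]]))
  invisible(x)
}

#' @export
summary.wdd <- function(object, ...) {
  rep <- weight_report(object)
  met <- confusion_and_metrics(object$train_scores, object$train_labels,
                               object$threshold)
  auc <- roc_auc(object$train_scores, object$train_labels)
  out <- list(model = object, weights = rep, train_metrics = met,
              train_auc = auc)
  class(out) <- "summary.wdd"
  out
}

#' @export
print.summary.wdd <- function(x, ...) {
  print(x$model)
  m <- x$train_metrics
  cat(sprintf("\nTraining fit (threshold %.4g):\n", x$model$threshold))
  cat(sprintf("  AUC %.4f | ACC %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$train_auc, m$acc, m$precision, m$recall, m$f1))
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n",
              m$tp, m$fp, m$fn, m$tn))
  cat("\nFeature weights (normalized, descending):\n")
  w <- x$weights[order(x$weights$rank), ]
  print(utils::head(data.frame(feature = w$feature,
                               weight = round(w$normalized_weight, 4)), 10),
        row.names = FALSE)
  invisible(x)
}

#' Extract model coefficients
#'
#' @param object A fitted [wdd()] model.
#' @param what `"weights"` (fitted nonnegative feature weights `s`) or
#'   `"prototype"` (the optimal point `x` in normalized feature space).
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.wdd <- function(object, what = c("weights", "prototype"), ...) {
  switch(match.arg(what), weights = object$weights,
         prototype = object$prototype)
}

#' Diagnostic plots for a fitted WDD model
#'
#' Draws the best-seen training-loss trajectory and the class-conditional
#' training risk-score distributions with the decision threshold.
#'
#' @param x A fitted [wdd()] model.
#' @param which Integer subset of `1:2`.
#' @param ... Passed to plotting primitives.
#' @export
plot.wdd <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                   xlab = "epoch", ylab = "best training loss",
                   main = sprintf("WDD-%s optimization", toupper(x$variant)),
                   ...)
  }
  if (2 %in% which && !is.null(x$train_scores)) {
    s1 <- x$train_scores[x$train_labels == 1L]
    s0 <- x$train_scores[x$train_labels == 0L]
    br <- pretty(range(x$train_scores), 40)
    h1 <- graphics::hist(s1, breaks = br, plot = FALSE)
    h0 <- graphics::hist(s0, breaks = br, plot = FALSE)
    ylim <- c(0, max(h1$counts, h0$counts))
    graphics::plot(h0, col = grDevices::adjustcolor("steelblue", 0.5),
                   ylim = ylim, xlab = "risk score", main = "Training scores")
    graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.5),
                   add = TRUE)
    graphics::abline(v = x$threshold, lty = 2)
    graphics::legend("topright", fill = c("steelblue", "firebrick"),
                     legend = c("negative", "positive"), bty = "n")
  }
  invisible(x)
}

#' Grid search over WDD hyperparameters
#'
#' Evaluates hyperparameter combinations by held-out AUC on a stratified
#' split of the cohort and returns the grid with scores attached.
#'
#' @param cohort A [wdd_cohort()].
#' @param variant Model variant.
#' @param gamma,delta,lambda Candidate values (vectors).
#' @param test_fraction Held-out fraction.
#' @param seed Split seed.
#' @param ... Passed to [wdd()].
#' @return Data frame of combinations with an `auc` column, best first.
#' @export
wdd_tune <- function(cohort, variant = "di", gamma = c(0.5, 1, 2),
                     delta = 1, lambda = 1, test_fraction = 0.2,
                     seed = 1, ...) {
  grid <- expand.grid(gamma = gamma, delta = delta, lambda = lambda)
  sp <- holdout_split(cohort, test_fraction, seed = seed)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- wdd(sp$dev, variant = variant, gamma = grid$gamma[i],
               delta = grid$delta[i], lambda = grid$lambda[i], ...)
    roc_auc(predict(fit, sp$test), sp$test$labels)
  }, numeric(1))
  grid[order(-grid$auc), ]
}
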