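# Interpretability: normalized weight reports, top-fraction feature sets,
# cross-model consensus, per-feature risk decompositions, and the
# Mann-Whitney feature screen.

#' Normalized feature-weight report
#'
#' Normalizes the fitted nonnegative weights to sum to 1 and ranks features
#' by descending normalized weight (ties broken by input feature order, so
#' the ranking is stable).
#'
#' @param model A fitted [wdd()] model.
#' @return A data frame of class `wdd_weights` with columns `feature`,
#'   `raw_weight`, `normalized_weight`, `rank`.
#' @export
weight_report <- function(model) {
  w <- model$weights
  if (all(w == 0)) stopf("all feature weights are zero (collapsed or untrained model)")
  nw <- w / sum(w)
  ord <- order(-nw, seq_along(nw))
  rank <- integer(length(nw)); rank[ord] <- seq_along(nw)
  out <- data.frame(feature = model$feature_names, raw_weight = as.numeric(w),
                    normalized_weight = as.numeric(nw), rank = rank,
                    stringsAsFactors = FALSE)
  class(out) <- c("wdd_weights", "data.frame")
  out
}

#' Top fraction of features by weight
#'
#' Returns the `ceiling(fraction * f)` highest-ranked features of a weight
#' report (the "important feature" rule: top 25% by normalized weight).
#'
#' @param report A `wdd_weights` report or a fitted [wdd()] model.
#' @param fraction Fraction in `(0, 1]`.
#' @return Integer vector of feature indices, named by feature.
#' @export
top_fraction_features <- function(report, fraction = 0.25) {
  stopifnot(fraction > 0, fraction <= 1)
  if (inherits(report, "wdd")) report <- weight_report(report)
  n_top <- ceiling(fraction * nrow(report))
  idx <- which(report$rank <= n_top)
  idx <- idx[order(report$rank[idx])]
  stats::setNames(idx, report$feature[idx])
}

#' Consensus important features across models
#'
#' Features falling in the top `fraction` by weight of at least `min_models`
#' of the supplied models/reports.
#'
#' @param reports List of `wdd_weights` reports or fitted [wdd()] models
#'   sharing a feature namespace.
#' @param fraction Top fraction per model.
#' @param min_models Minimum number of models that must select a feature
#'   (default: all of them).
#' @return Integer vector of feature indices, named by feature.
#' @export
consensus_features <- function(reports, fraction = 0.25,
                               min_models = length(reports)) {
  stopifnot(length(reports) >= 1, min_models <= length(reports))
  reports <- lapply(reports, function(r)
    if (inherits(r, "wdd")) weight_report(r) else r)
  feats <- reports[[1]]$feature
  for (r in reports[-1])
    if (!identical(r$feature, feats))
      stopf("reports do not share a feature namespace")
  counts <- Reduce(`+`, lapply(reports, function(r) {
    sel <- logical(length(feats))
    sel[top_fraction_features(r, fraction)] <- TRUE
    sel
  }))
  idx <- which(counts >= min_models)
  stats::setNames(idx, feats[idx])
}

#' Per-feature, per-class risk-contribution summary
#'
#' Summarizes the distribution of each feature's contribution `dist_k` to the
#' sample risk scores, separately for the positive and negative class
#' (mean, median and quartiles), as used for raincloud-style comparisons of
#' which features the model separates the classes on. Missing features
#' contribute nothing to a sample's entries.
#'
#' @param model A fitted [wdd()] model.
#' @param cohort A labeled [wdd_cohort()].
#' @return Data frame with one row per feature x class: columns `feature`,
#'   `class`, `mean`, `q1`, `median`, `q3`.
#' @export
group_distk_summary <- function(model, cohort) {
  rep <- risk_report(model, cohort)
  labs <- cohort$labels
  out <- list()
  for (cls in c(1L, 0L)) {
    dk <- rep$distk[labs == cls, , drop = FALSE]
    qs <- apply(dk, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE)
    out[[as.character(cls)]] <- data.frame(
      feature = model$feature_names,
      class = ifelse(cls == 1L, "positive", "negative"),
      mean = colMeans(dk), q1 = qs[1, ], median = qs[2, ], q3 = qs[3, ],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Mann-Whitney U screen for a single feature
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the observed
#' values of one feature between the positive and negative class, using the
#' normal approximation with tie and continuity correction.
#'
#' @param cohort A labeled [wdd_cohort()].
#' @param feature Feature name or column index.
#' @return List with `statistic` (U for the positive class), `p_value`, and
#'   the per-class observation counts.
#' @export
feature_difference_test <- function(cohort, feature) {
  j <- if (is.character(feature)) match(feature, cohort$feature_names)
  else as.integer(feature)
  if (is.na(j) || j < 1 || j > ncol(cohort$values))
    stopf("unknown feature: %s", feature)
  v <- cohort$values[, j]
  xp <- v[cohort$labels == 1L & !is.na(v)]
  xn <- v[cohort$labels == 0L & !is.na(v)]
  if (!length(xp) || !length(xn))
    stopf("feature '%s' has no observed values in one class",
          cohort$feature_names[j])
  ht <- stats::wilcox.test(xp, xn, exact = FALSE, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_pos = length(xp), n_neg = length(xn))
}
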