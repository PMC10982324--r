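# Preprocessing: robust normalization with IQR outlier nulling, degenerate
# feature removal, KNN imputation, class-balanced missingness equalization.

#' Fit robust normalization statistics
#'
#' For every feature, computes Q1/Q3 over observed values (linear-interpolation
#' quantiles, `type = 7`), Tukey fences at 1.5 IQR, and the mean and sample SD
#' of the observed values *inside* the fences. Features whose in-fence SD is 0
#' (constant features) are flagged `kept = FALSE` and dropped when the
#' statistics are applied.
#'
#' @param cohort A [wdd_cohort()] or numeric matrix with `NA` for missing.
#' @return An object of class `wdd_norm`: a data frame with columns `feature`,
#'   `mu`, `sigma`, `q1`, `q3`, `lower_fence`, `upper_fence`, `kept`.
#' @export
fit_robust_stats <- function(cohort) {
  values <- if (inherits(cohort, "wdd_cohort")) cohort$values else
    as.matrix(cohort)
  f <- ncol(values)
  fn <- colnames(values) %||% sprintf("feat_%02d", seq_len(f))
  out <- data.frame(feature = fn, mu = NA_real_, sigma = NA_real_,
                    q1 = NA_real_, q3 = NA_real_, lower_fence = NA_real_,
                    upper_fence = NA_real_, kept = TRUE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(f)) {
    v <- values[, j]
    v <- v[!is.na(v)]
    if (!length(v)) stopf("feature '%s' has no observed values", fn[j])
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    inl <- v[v >= lo & v <= hi]
    mu <- mean(inl)
    sigma <- if (length(inl) > 1) stats::sd(inl) else 0
    out$mu[j] <- mu; out$sigma[j] <- sigma
    out$q1[j] <- q[1]; out$q3[j] <- q[2]
    out$lower_fence[j] <- lo; out$upper_fence[j] <- hi
    out$kept[j] <- sigma > 0
  }
  class(out) <- c("wdd_norm", "data.frame")
  out
}

#' Apply fitted normalization statistics to a cohort
#'
#' Drops features flagged `kept = FALSE`, optionally masks observed values
#' outside the Tukey fences as missing (outlier nulling), and transforms the
#' remaining observed values to `(x - mu) / sigma`. Missing entries stay
#' missing.
#'
#' @param cohort A [wdd_cohort()].
#' @param stats A `wdd_norm` from [fit_robust_stats()].
#' @param null_outliers Mask out-of-fence values as missing before scaling
#'   (the standard first-pass behaviour). Set `FALSE` for the re-normalization
#'   pass after imputation.
#' @return A normalized [wdd_cohort()].
#' @export
apply_normalization <- function(cohort, stats, null_outliers = TRUE) {
  stopifnot(inherits(stats, "wdd_norm"))
  if (!identical(cohort$feature_names, stats$feature))
    stopf("cohort feature names do not match the fitted statistics")
  keep <- which(stats$kept)
  if (!length(keep)) stopf("all features are degenerate (sigma = 0)")
  values <- cohort$values[, keep, drop = FALSE]
  st <- stats[keep, ]
  if (null_outliers) {
    out_lo <- sweep(values, 2, st$lower_fence, `<`)
    out_hi <- sweep(values, 2, st$upper_fence, `>`)
    values[!is.na(values) & (out_lo | out_hi)] <- NA_real_
  }
  values <- sweep(sweep(values, 2, st$mu, `-`), 2, st$sigma, `/`)
  out <- wdd_cohort(values, cohort$labels, age = cohort$age,
                    sex = cohort$sex, feature_names = st$feature)
  attr(out, "informative") <- attr(cohort, "informative")
  out
}

#' Drop degenerate (zero-variance) features
#'
#' @param cohort A [wdd_cohort()].
#' @param stats A `wdd_norm` from [fit_robust_stats()].
#' @return The cohort restricted to `kept` features, order preserved.
#' @export
drop_degenerate_features <- function(cohort, stats) {
  stopifnot(inherits(stats, "wdd_norm"))
  keep <- which(stats$kept)
  if (!length(keep)) stopf("all features are degenerate (sigma = 0)")
  out <- wdd_cohort(cohort$values[, keep, drop = FALSE], cohort$labels,
                    age = cohort$age, sex = cohort$sex,
                    feature_names = cohort$feature_names[keep])
  attr(out, "informative") <- attr(cohort, "informative")
  out
}

# Missing-aware squared Euclidean distances between rows of `a` and rows of
# `b`, per the nan-Euclidean contract: mean squared difference over mutually
# observed coordinates, rescaled to the full feature count. Returns the
# rescaled squared distance matrix plus the mutual-observation counts.
nan_euclidean_dist2 <- function(a, b) {
  f <- ncol(a)
  ma <- !is.na(a); mb <- !is.na(b)
  a0 <- a; a0[!ma] <- 0
  b0 <- b; b0[!mb] <- 0
  # sum over mutual k of (a_ik - b_jk)^2, via three cross-products
  pa <- (a0 * a0) %*% t(mb)          # sum a^2 over mutual
  pb <- ma %*% t(b0 * b0)            # sum b^2 over mutual
  cross <- a0 %*% t(b0)
  d2 <- pa + pb - 2 * cross
  d2[d2 < 0] <- 0                    # numerical noise
  cnt <- ma %*% t(mb)
  d2 <- f * d2 / cnt
  d2[cnt == 0] <- Inf
  list(d2 = d2, count = cnt)
}

# Core donor-mean imputation used by knn_impute and by prediction-time
# imputation against a stored reference matrix.
impute_against <- function(target, donors, k) {
  miss_rows <- which(rowSums(is.na(target)) > 0)
  if (!length(miss_rows)) return(target)
  if (any(rowSums(!is.na(target)) == 0))
    stopf("sample(s) with zero observed features cannot be imputed: %s",
          paste(which(rowSums(!is.na(target)) == 0), collapse = ", "))
  dd <- nan_euclidean_dist2(target[miss_rows, , drop = FALSE], donors)
  donor_obs <- !is.na(donors)
  miss_cells <- is.na(target)
  for (ii in seq_along(miss_rows)) {
    i <- miss_rows[ii]
    ord <- order(dd$d2[ii, ])
    for (j in which(miss_cells[i, ])) {
      cand <- ord[donor_obs[ord, j]]
      if (!length(cand)) stopf("feature %d has no observed donor values", j)
      use <- cand[seq_len(min(k, length(cand)))]
      target[i, j] <- mean(donors[use, j])
    }
  }
  target
}

#' K-nearest-neighbour imputation
#'
#' Replaces each missing entry by the unweighted mean of that feature over the
#' `k` nearest samples observing it, with nearness measured by missing-aware
#' Euclidean distance (mean squared difference over mutually observed
#' features, rescaled to full dimension). When fewer than `k` donors observe
#' the feature, all available donors are used. After imputation the matrix is
#' re-normalized by a fresh [fit_robust_stats()] + [apply_normalization()]
#' pass with outlier nulling disabled, so the output contains no missing
#' entries.
#'
#' A sample imputes from the other samples of the cohort (itself excluded as a
#' donor for its own missing entries by the infinite self-distance of a
#' missing coordinate being irrelevant: the self row is included in the donor
#' pool but contributes nothing for features it does not observe, and a
#' sample never donates to a feature it is missing).
#'
#' @param cohort A [wdd_cohort()] (typically already normalized).
#' @param k Number of donor neighbours (default 15).
#' @param renormalize Re-fit and re-apply normalization statistics after
#'   imputation (default `TRUE`).
#' @return A complete [wdd_cohort()] (no `NA`), plus attribute `norm2` holding
#'   the second-pass statistics when `renormalize = TRUE`.
#' @export
knn_impute <- function(cohort, k = 15, renormalize = TRUE) {
  stopifnot(k >= 1)
  values <- cohort$values
  if (anyNA(values)) values <- impute_against(values, cohort$values, k)
  out <- wdd_cohort(values, cohort$labels, age = cohort$age,
                    sex = cohort$sex, feature_names = cohort$feature_names)
  attr(out, "informative") <- attr(cohort, "informative")
  if (renormalize && anyNA(cohort$values)) {
    st2 <- fit_robust_stats(out)
    out2 <- apply_normalization(out, st2, null_outliers = FALSE)
    attr(out2, "norm2") <- st2
    attr(out2, "informative") <- attr(cohort, "informative")
    return(out2)
  }
  out
}

#' Equalize per-feature missingness between classes
#'
#' For each feature, the class with the lower missing rate has uniformly
#' random observed entries additionally masked until both classes' missing
#' rates agree up to integer resolution. Entries are only ever masked, never
#' restored, so the output mask is a subset of the input mask. This removes
#' class-informative missingness patterns before fitting the
#' missing-value-tolerant model variants.
#'
#' @param cohort A [wdd_cohort()] with both classes present.
#' @param seed Integer seed for the random masking, or `NULL`.
#' @return A [wdd_cohort()] with balanced per-feature class missing rates.
#' @export
equalize_class_missingness <- function(cohort, seed = NULL) {
  pos <- which(cohort$labels == 1L)
  neg <- which(cohort$labels == 0L)
  if (!length(pos) || !length(neg))
    stopf("both classes must be present to equalize missingness")
  run <- function() {
    values <- cohort$values
    for (j in seq_len(ncol(values))) {
      r_pos <- mean(is.na(values[pos, j]))
      r_neg <- mean(is.na(values[neg, j]))
      if (r_pos == r_neg) next
      if (r_pos < r_neg) { idx <- pos; target_rate <- r_neg }
      else               { idx <- neg; target_rate <- r_pos }
      n_cls <- length(idx)
      want_missing <- round(target_rate * n_cls)
      extra <- want_missing - sum(is.na(values[idx, j]))
      if (extra <= 0) next
      obs <- idx[!is.na(values[idx, j])]
      hide <- if (length(obs) == 1) obs else
        sample(obs, min(extra, length(obs)))
      values[hide, j] <- NA_real_
    }
    out <- wdd_cohort(values, cohort$labels, age = cohort$age,
                      sex = cohort$sex,
                      feature_names = cohort$feature_names)
    attr(out, "informative") <- attr(cohort, "informative")
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
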