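# Elementary WDD operations: weighted squared distances, class-membership
# probabilities for the three variants, the negative log-likelihood and its
# analytic gradient. All functions are vectorized over samples.

#' Weighted squared distance to the prototype
#'
#' Computes `sum_k s_k (b_k - x_k)^2` over observed features for each sample;
#' missing features contribute exactly 0. Also returns the per-sample count of
#' missing features.
#'
#' @param values Numeric matrix (samples x features), `NA` = missing.
#' @param x Prototype vector (length f).
#' @param s Nonnegative feature-weight vector (length f).
#' @return List with `dist` (length-n vector) and `f_miss` (integer vector).
#' @export
weighted_sq_dist <- function(values, x, s) {
  values <- rbind(values)  # promote a single sample to a 1-row matrix
  if (ncol(values) != length(x) || length(x) != length(s))
    stopf("dimension mismatch between values, x and s")
  if (any(s < 0)) stopf("feature weights must be nonnegative")
  d <- sweep(values, 2, x, `-`)
  miss <- is.na(d)
  d[miss] <- 0
  list(dist = as.vector((d * d) %*% s),
       f_miss = as.integer(rowSums(miss)))
}

#' Class-membership probabilities, imputation (KNN) variant
#'
#' `pr_pos = exp(-gamma * dist)`, `pr_neg = 1 - pr_pos`.
#'
#' @param dist Nonnegative distance(s).
#' @param gamma Positive scale hyperparameter.
#' @return List with `pr_pos` and `pr_neg` (vectors in `[0, 1]`).
#' @export
kn_probs <- function(dist, gamma = 1) {
  stopifnot(gamma > 0)
  a <- gamma * dist
  list(pr_pos = exp(-a), pr_neg = -expm1(-a))
}

#' Class-membership probabilities, division-penalty (DI) variant
#'
#' `pr_pos = exp(-gamma * dist / (f - f_miss)^delta)`. The division penalty
#' shrinks the diversity density of samples with many missing features; with
#' no missing features it reduces to the KNN variant at `gamma / f^delta`.
#'
#' @param dist Nonnegative distance(s) (missing features contribute 0).
#' @param f Total feature count.
#' @param f_miss Missing-feature count(s), `0 <= f_miss < f`.
#' @param gamma,delta Positive hyperparameters.
#' @return List with `pr_pos` and `pr_neg`.
#' @export
di_probs <- function(dist, f, f_miss, gamma = 1, delta = 1) {
  stopifnot(gamma > 0, delta > 0)
  if (any(f_miss >= f))
    stopf("sample with all %d features missing: DI probability undefined", f)
  a <- gamma * dist / (f - f_miss)^delta
  list(pr_pos = exp(-a), pr_neg = -expm1(-a))
}

#' Bounded similarity, feature-ignoring (BF) variant
#'
#' Per-feature similarity `Dist'_k = exp(-gamma * s_k * |b_k - x_k|)` for
#' observed features (0 for missing ones), aggregated as
#' `sim = sum_k (Dist'_k)^lambda`. Larger values mean closer to the prototype;
#' missing features are simply ignored (contribute 0).
#'
#' @inheritParams weighted_sq_dist
#' @param gamma,lam Positive hyperparameters.
#' @return List with `sim` (length-n) and `terms` (n x f matrix of
#'   `(Dist'_k)^lambda`, 0 at missing entries).
#' @export
bf_similarity <- function(values, x, s, gamma = 1, lam = 1) {
  values <- rbind(values)
  stopifnot(gamma > 0, lam > 0)
  if (any(s < 0)) stopf("feature weights must be nonnegative")
  d <- abs(sweep(values, 2, x, `-`))
  miss <- is.na(d)
  d[miss] <- 0
  terms <- exp(-lam * gamma * sweep(d, 2, s, `*`))
  terms[miss] <- 0
  list(sim = as.vector(rowSums(terms)), terms = terms)
}

#' Class-membership probabilities, BF variant
#'
#' `pr_pos = 1 - exp(-sim)`, `pr_neg = exp(-sim)`: probability of the positive
#' class increases with similarity to the prototype, and a sample with no
#' observed features (sim = 0) gets `pr_pos = 0`.
#'
#' @param sim Nonnegative similarity from [bf_similarity()].
#' @return List with `pr_pos` and `pr_neg`.
#' @export
bf_probs <- function(sim) {
  stopifnot(all(sim >= 0))
  list(pr_pos = -expm1(-sim), pr_neg = exp(-sim))
}

# ---------------------------------------------------------------------------
# Loss and analytic gradient. Parameters are theta = c(x, raw_s) with
# s = softplus(raw_s). The log-likelihood is computed in log space: terms
# whose log is analytically exact (-log exp(-a) = a) are never floored, so
# far-from-prototype samples keep a training gradient even when exp(-a)
# underflows; terms of the form -log(1 - exp(-a)) are singular as a -> 0 and
# are floored at prob_floor, with zero gradient when floored (the floored
# value is locally constant, keeping the analytic gradient consistent with
# finite differences of the actual loss).

wdd_loss_grad <- function(values, labels, theta, variant, gamma, delta, lam,
                          prob_floor = 1e-12, want_grad = TRUE) {
  f <- ncol(values)
  x <- theta[seq_len(f)]
  raw <- theta[f + seq_len(f)]
  s <- softplus(raw)
  pos <- labels == 1L
  d <- sweep(values, 2, x, `-`)
  miss <- is.na(d)
  d[miss] <- 0

  if (variant %in% c("knn", "di")) {
    d2 <- d * d
    dist <- as.vector(d2 %*% s)
    pen <- if (variant == "di") {
      fm <- rowSums(miss)
      if (any(fm >= f))
        stopf("sample with all features missing: DI loss undefined")
      (f - fm)^delta
    } else rep(1, nrow(values))
    a <- gamma * dist / pen
    p_neg <- -expm1(-a)
    # positives: -log exp(-a) = a, exact; negatives: floored at prob_floor
    term <- ifelse(pos, a, -log(pmax(p_neg, prob_floor)))
    loss <- sum(term)
    if (!want_grad) return(list(loss = loss))
    # dL/da per sample; floored negative terms are locally constant
    g <- numeric(length(a))
    g[pos] <- gamma
    na_idx <- !pos & p_neg > prob_floor
    g[na_idx] <- -gamma * exp(-a[na_idx]) / p_neg[na_idx]
    w <- g / pen
    grad_x <- -2 * s * as.vector(t(d) %*% w)
    grad_s <- as.vector(t(d2) %*% w)
  } else { # bf
    ad <- abs(d)
    terms <- exp(-lam * gamma * sweep(ad, 2, s, `*`))
    terms[miss] <- 0
    sim <- rowSums(terms)
    p_pos <- -expm1(-sim)
    # negatives: -log exp(-sim) = sim, exact; positives floored
    term <- ifelse(pos, -log(pmax(p_pos, prob_floor)), sim)
    loss <- sum(term)
    if (!want_grad) return(list(loss = loss))
    g <- numeric(length(sim))           # dL/dsim
    pa <- pos & p_pos > prob_floor
    g[pa] <- -exp(-sim[pa]) / p_pos[pa]
    g[!pos] <- 1
    # dsim/dx_k = lam*gamma*s_k * sum_i terms_ik * sign(d_ik)
    grad_x <- lam * gamma * s * as.vector(t(terms * sign(d)) %*% g)
    grad_s <- -lam * gamma * as.vector(t(terms * ad) %*% g)
  }
  list(loss = loss, grad = c(grad_x, grad_s * sigmoid(raw)))
}

#' Negative log-likelihood of a WDD model on a cohort
#'
#' `-sum_pos log pr_pos - sum_neg log pr_neg`, computed in log space.
#' Terms with an exact log form (`-log exp(-a) = a`) are evaluated directly;
#' terms of the form `-log(1 - exp(-a))`, which diverge as `a -> 0`, have the
#' probability floored at `prob_floor` before the logarithm.
#'
#' @param cohort A [wdd_cohort()] containing both classes.
#' @param x Prototype vector.
#' @param s Nonnegative weight vector.
#' @param variant `"knn"`, `"di"` or `"bf"`.
#' @param gamma,delta,lam Hyperparameters.
#' @param prob_floor Clipping floor for log safety.
#' @return The scalar loss.
#' @export
nll_loss <- function(cohort, x, s, variant = c("knn", "di", "bf"),
                     gamma = 1, delta = 1, lam = 1, prob_floor = 1e-12) {
  variant <- match.arg(variant)
  if (!any(cohort$labels == 1L) || !any(cohort$labels == 0L))
    stopf("nll_loss requires both classes (the likelihood over an empty class is degenerate)")
  theta <- c(x, softplus_inv(pmax(s, 1e-10)))
  wdd_loss_grad(cohort$values, cohort$labels, theta, variant, gamma, delta,
                lam, prob_floor, want_grad = FALSE)$loss
}

# Full-batch Adam on theta = c(x, raw_s); returns best-loss parameters seen.
adam_fit <- function(values, labels, theta0, variant, gamma, delta, lam,
                     control) {
  theta <- theta0
  m <- v <- numeric(length(theta))
  b1 <- control$adam_beta1; b2 <- control$adam_beta2
  eps <- control$adam_eps; lr <- control$learning_rate
  best <- wdd_loss_grad(values, labels, theta, variant, gamma, delta, lam,
                        control$prob_floor, want_grad = FALSE)$loss
  if (!is.finite(best))
    stopf("non-finite loss at initialization (variant %s)", variant)
  best_theta <- theta
  history <- numeric(control$epochs)
  last_improve <- best
  epochs_run <- 0L
  for (t in seq_len(control$epochs)) {
    lg <- wdd_loss_grad(values, labels, theta, variant, gamma, delta, lam,
                        control$prob_floor)
    if (!is.finite(lg$loss)) stopf("non-finite loss at epoch %d", t)
    if (lg$loss < best) { best <- lg$loss; best_theta <- theta }
    history[t] <- best
    m <- b1 * m + (1 - b1) * lg$grad
    v <- b2 * v + (1 - b2) * lg$grad^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    theta <- theta - lr * mh / (sqrt(vh) + eps)
    epochs_run <- t
    if (control$convergence_tol > 0 && t %% 25 == 0) {
      if (abs(last_improve - best) <= control$convergence_tol *
            (abs(best) + 1e-8)) break
      last_improve <- best
    }
  }
  list(theta = best_theta, loss = best, history = history[seq_len(epochs_run)],
       epochs_run = epochs_run)
}

#' Training configuration for [wdd()]
#'
#' @param learning_rate Adam/SGD step size.
#' @param epochs Maximum full-batch epochs.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param init_x Prototype initialization: `"pos_mean"` (per-feature mean of
#'   positive-class observed values) or `"zeros"`.
#' @param init_s Initial feature weight (applied through the softplus
#'   reparameterization).
#' @param prob_floor Probability clipping floor before logarithms.
#' @param convergence_tol Relative improvement tolerance checked every 25
#'   epochs; 0 disables early stopping.
#' @param impute_k Donor count for KNN imputation (KNN variant).
#' @param seed Seed for the (seeded) missingness-equalization step.
#' @return A list of class `wdd_control`.
#' @export
wdd_control <- function(learning_rate = 0.05, epochs = 500,
                        optimizer = c("adam", "sgd"),
                        adam_beta1 = 0.9, adam_beta2 = 0.999,
                        adam_eps = 1e-8,
                        init_x = c("pos_mean", "zeros"), init_s = 1,
                        prob_floor = 1e-12, convergence_tol = 0,
                        impute_k = 15, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, init_s > 0,
            prob_floor > 0, prob_floor <= 1e-3, convergence_tol >= 0)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 optimizer = match.arg(optimizer),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, init_x = match.arg(init_x),
                 init_s = init_s, prob_floor = prob_floor,
                 convergence_tol = convergence_tol, impute_k = impute_k,
                 seed = as.integer(seed)),
            class = "wdd_control")
}

sgd_fit <- function(values, labels, theta0, variant, gamma, delta, lam,
                    control) {
  theta <- theta0
  best <- Inf; best_theta <- theta
  history <- numeric(control$epochs)
  for (t in seq_len(control$epochs)) {
    lg <- wdd_loss_grad(values, labels, theta, variant, gamma, delta, lam,
                        control$prob_floor)
    if (!is.finite(lg$loss)) stopf("non-finite loss at epoch %d", t)
    if (lg$loss < best) { best <- lg$loss; best_theta <- theta }
    history[t] <- best
    theta <- theta - control$learning_rate * lg$grad
  }
  list(theta = best_theta, loss = best, history = history,
       epochs_run = control$epochs)
}
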