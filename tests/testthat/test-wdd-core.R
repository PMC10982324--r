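# Core WDD operations: distances, the three probability families, the loss
# and its analytic gradient, model fitting, risk scoring, thresholding.

test_that("weighted squared distance handles missing features as zero contribution", {
  x <- c(1, 2); s <- c(0.5, 0.5)
  expect_equal(weighted_sq_dist(rbind(c(1, 2)), x, s),
               list(dist = 0, f_miss = 0L))
  d <- weighted_sq_dist(rbind(c(2, 4)), x, s)    # diffs (1, 2)
  expect_equal(d$dist, 0.5 * 1 + 0.5 * 4)
  all_na <- weighted_sq_dist(rbind(c(NA_real_, NA_real_)), x, s)
  expect_equal(all_na, list(dist = 0, f_miss = 2L))
  expect_error(weighted_sq_dist(rbind(c(1, 2)), x, c(-1, 1)), "nonnegative")
})

test_that("KNN-variant probabilities follow exp(-gamma d) and sum to one", {
  expect_equal(kn_probs(0, 1), list(pr_pos = 1, pr_neg = 0))
  p <- kn_probs(log(2), 1)
  expect_equal(p$pr_pos, 0.5)
  expect_equal(p$pr_neg, 0.5)
  p2 <- kn_probs(0.5, 2)
  expect_equal(p2$pr_pos, exp(-1))
  expect_equal(p2$pr_neg, 1 - exp(-1))
  d <- runif(50, 0, 10)
  p3 <- kn_probs(d, 0.7)
  expect_true(all(p3$pr_pos >= 0 & p3$pr_pos <= 1))
  expect_equal(p3$pr_pos + p3$pr_neg, rep(1, 50))
})

test_that("DI probabilities: division penalty, degenerate error, KNN reduction", {
  p <- di_probs(5, f = 10, f_miss = 0, gamma = 1, delta = 1)
  expect_equal(p$pr_pos, exp(-0.5), tolerance = 1e-12)
  expect_error(di_probs(1, f = 4, f_miss = 4), "missing")
  # delta -> 0 recovers the unpenalized form
  p0 <- di_probs(3, f = 7, f_miss = 2, gamma = 1.3, delta = 1e-14)
  expect_equal(p0$pr_pos, kn_probs(3, 1.3)$pr_pos, tolerance = 1e-10)
  # with zero missing, DI == KNN at gamma' = gamma / f^delta (float exact)
  set.seed(1)
  for (i in 1:100) {
    d <- runif(1, 0, 20); f <- sample(2:40, 1)
    gamma <- runif(1, 0.2, 3); delta <- runif(1, 0.2, 2)
    expect_equal(di_probs(d, f, 0, gamma, delta)$pr_pos,
                 kn_probs(d, gamma / f^delta)$pr_pos, tolerance = 1e-12)
  }
  # penalty direction: pr_pos strictly decreasing in f_miss at fixed dist
  pr <- sapply(0:9, function(fm) di_probs(4, 10, fm, 1, 1)$pr_pos)
  expect_true(all(diff(pr) < 0))
})

test_that("BF similarity ignores missing features and composes with its probabilities", {
  f <- 10
  x <- rnorm(f); s <- runif(f, 0.5, 2)
  bs <- bf_similarity(rbind(x), x, s, gamma = 1, lam = 1)
  expect_equal(bs$sim, f)                       # every term exp(0) = 1
  expect_equal(bf_probs(bs$sim)$pr_pos, 1 - exp(-f))
  all_na <- bf_similarity(rbind(rep(NA_real_, f)), x, s)
  expect_equal(all_na$sim, 0)
  expect_equal(bf_probs(0), list(pr_pos = 0, pr_neg = 1))
  p <- bf_probs(log(2))
  expect_equal(p$pr_pos, 0.5)
  # monotone decreasing in each |diff|
  sims <- sapply(c(0.1, 1, 5, 50), function(sc)
    bf_similarity(rbind(x + sc), x, s)$sim)
  expect_true(all(diff(sims) < 0))
  expect_lt(sims[4], 1e-8)
})

test_that("risk ordering is monotone: pr_pos decreasing in dist (KNN/DI), increasing in sim (BF)", {
  d <- sort(runif(30, 0, 10))
  expect_true(all(diff(kn_probs(d, 1.5)$pr_pos) < 0))
  expect_true(all(diff(di_probs(d, 8, 2, 1, 1)$pr_pos) < 0))
  sm <- sort(runif(30, 0, 10))
  expect_true(all(diff(bf_probs(sm)$pr_pos) > 0))
})

test_that("the loss matches closed forms and a term-by-term oracle", {
  # one positive at pr_pos 0.5 and one negative at pr_neg 0.5 -> 2 log 2
  v <- matrix(c(sqrt(log(2)), sqrt(log(2))), 2, 1)
  coh <- wdd_cohort(v, c(1, 0))
  expect_equal(nll_loss(coh, x = 0, s = 1, variant = "knn"), 2 * log(2),
               tolerance = 1e-10)
  expect_error(nll_loss(wdd_cohort(v, c(1, 1)), 0, 1, "knn"), "both classes")

  # random instance: loss equals the sum over samples of -log(prob) with the
  # probabilities recomputed from the elementary operations
  set.seed(10)
  vals <- matrix(rnorm(100), 20, 5)
  vals[sample(100, 10)] <- NA
  labs <- rep(c(1L, 0L), 10)
  coh <- wdd_cohort(vals, labs)
  x <- rnorm(5); s <- runif(5, 0.2, 2)
  gamma <- 0.8; delta <- 1.4; lam <- 1.1
  clip <- function(p) pmax(p, 1e-12)   # floor only; logs are otherwise exact
  ws <- weighted_sq_dist(vals, x, s)
  for (variant in c("knn", "di", "bf")) {
    pr <- switch(variant,
      knn = kn_probs(ws$dist, gamma),
      di = di_probs(ws$dist, 5, ws$f_miss, gamma, delta),
      bf = bf_probs(bf_similarity(vals, x, s, gamma, lam)$sim))
    oracle <- -sum(log(clip(ifelse(labs == 1L, pr$pr_pos, pr$pr_neg))))
    expect_equal(nll_loss(coh, x, s, variant, gamma, delta, lam), oracle,
                 tolerance = 1e-8)
  }
})

test_that("analytic gradients match central finite differences", {
  h <- 1e-5
  for (seed in 1:3) {
    set.seed(seed)
    vals <- matrix(rnorm(100), 20, 5)
    vals[sample(100, 8)] <- NA
    labs <- rep(c(1L, 0L), 10)
    theta <- rnorm(10, sd = 0.8)
    for (variant in c("knn", "di", "bf")) {
      lg <- wddscreen:::wdd_loss_grad(vals, labs, theta, variant,
                                      0.7, 1.2, 0.9)
      fd <- vapply(seq_along(theta), function(i) {
        tp <- theta; tp[i] <- tp[i] + h
        tm <- theta; tm[i] <- tm[i] - h
        (wddscreen:::wdd_loss_grad(vals, labs, tp, variant, 0.7, 1.2, 0.9,
                                   want_grad = FALSE)$loss -
         wddscreen:::wdd_loss_grad(vals, labs, tm, variant, 0.7, 1.2, 0.9,
                                   want_grad = FALSE)$loss) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(lg$grad - fd) / pmax(abs(fd), 1e-8)), 1e-4)
    }
  }
})

test_that("fitting separable data recovers the signal; training loss decreases", {
  coh <- planted_cohort(150, 5, 5, shift_sd = 3, seed = 21)
  sp <- holdout_split(coh, 0.2, seed = 1)
  for (variant in c("knn", "di", "bf")) {
    fit <- wdd(sp$dev, variant = variant,
               control = wdd_control(epochs = 200))
    expect_true(all(diff(fit$loss_history) <= 0))  # best-seen is monotone
    expect_lt(fit$loss, fit$loss_history[1])
    auc <- roc_auc(predict(fit, sp$test), sp$test$labels)
    expect_gte(auc, 0.95)
  }
})

test_that("fitting is deterministic end to end", {
  coh <- planted_cohort(60, 6, 2, shift_sd = 1.5, missing_rate = 0.1,
                        seed = 33)
  a <- wdd(coh, variant = "di", control = wdd_control(epochs = 80))
  b <- wdd(coh, variant = "di", control = wdd_control(epochs = 80))
  expect_identical(a$weights, b$weights)
  expect_identical(a$prototype, b$prototype)
  expect_identical(a$threshold, b$threshold)
})

test_that("risk scores: prototype scores 1, decomposition is conserved, oracle recomposition", {
  f <- 6
  coh <- planted_cohort(40, f, 2, shift_sd = 1, missing_rate = 0.15,
                        seed = 12)
  for (variant in c("di", "bf")) {
    fit <- wdd(coh, variant = variant, control = wdd_control(epochs = 60),
               preprocess = FALSE)
    rep <- risk_report(fit, coh)
    expect_equal(unname(rowSums(rep$distk)), rep$dist, tolerance = 1e-12)
    # missing features contribute exactly 0 (MVT variants never impute)
    expect_true(all(rep$distk[is.na(coh$values)] == 0))
    # recomposition from elementary operations
    ws <- weighted_sq_dist(coh$values, fit$prototype, fit$weights)
    oracle <- switch(variant,
      di = exp(-fit$gamma * ws$dist / (f - ws$f_miss)^fit$delta),
      bf = bf_similarity(coh$values, fit$prototype, fit$weights,
                         fit$gamma, fit$lambda)$sim)
    expect_equal(rep$score, oracle, tolerance = 1e-12)
    expect_identical(rep$predicted,
                     as.integer(rep$score >= fit$threshold))
  }
  # KNN variant on complete data: recomposition plus score 1 at the prototype
  full <- planted_cohort(40, f, 2, shift_sd = 1, seed = 12)
  fit <- wdd(full, variant = "knn", control = wdd_control(epochs = 60),
             preprocess = FALSE)
  rep <- risk_report(fit, full)
  ws <- weighted_sq_dist(full$values, fit$prototype, fit$weights)
  expect_equal(rep$score, exp(-fit$gamma * ws$dist), tolerance = 1e-12)
  expect_equal(unname(rowSums(rep$distk)), rep$dist, tolerance = 1e-12)
  expect_equal(unname(predict(fit, rbind(fit$prototype))), 1)
})

test_that("Youden threshold matches exhaustive enumeration and its stated examples", {
  expect_equal(youden_threshold(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 0.8)
  # tie at J = 0.5 between cutoffs 0.35 and 0.8: smallest wins
  expect_equal(youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.35)
  expect_equal(youden_threshold(rep(0.7, 6), c(1, 0, 1, 0, 1, 0)), 0.7)
  expect_error(youden_threshold(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(31)
  for (i in 1:25) {
    sc <- round(runif(60), 2)          # ties on purpose
    lb <- rbinom(60, 1, 0.4)
    if (sum(lb) %in% c(0, 60)) next
    expect_equal(youden_threshold(sc, lb), brute_youden(sc, lb)$threshold)
  }
})

test_that("degenerate fits are refused with informative errors", {
  coh <- planted_cohort(20, 3, 1, seed = 2)
  expect_error(wdd(subset_cohort(coh, 1:20), variant = "di"),
               "both classes")
  # DI: an all-missing sample cannot be scored
  m <- coh$values
  m[1, ] <- NA
  bad <- wdd_cohort(m, coh$labels)
  expect_error(wdd(bad, variant = "di", preprocess = FALSE,
                   equalize = FALSE), "all features missing")
})
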