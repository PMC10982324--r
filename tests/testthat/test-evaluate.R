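# Evaluation: confusion metrics, rank AUC, stratified splitting, repeated
# cross-validation, subgroup modelling.

test_that("confusion metrics match the closed-form example and a brute tally", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.3, 0.2, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_and_metrics(scores, labels, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 1, 5))
  expect_equal(m$acc, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  # perfect classifier
  p <- confusion_and_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(c(p$acc, p$precision, p$recall, p$f1), rep(1, 4))
  # zero-division convention
  z <- confusion_and_metrics(c(0.1, 0.2), c(1, 0), 0.9)
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
  set.seed(3)
  for (i in 1:20) {
    sc <- runif(50); lb <- rbinom(50, 1, 0.5); th <- runif(1)
    b <- brute_confusion(sc, lb, th)
    m <- confusion_and_metrics(sc, lb, th)
    expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(b$tp, b$tn, b$fp, b$fn))
  }
})

test_that("rank AUC matches pairwise win counting, ties and transforms", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(1, 0), 4)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(5)
  sc <- round(runif(40), 1); lb <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(sc, lb), brute_auc(sc, lb))
  # invariance under strictly increasing transform; complement under negation
  expect_equal(roc_auc(exp(3 * sc), lb), roc_auc(sc, lb))
  expect_equal(roc_auc(sc, lb) + roc_auc(-sc, lb), 1)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(100); lb <- rbinom(100, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-12)
})

test_that("holdout split is stratified, seeded and a partition", {
  coh <- planted_cohort(50, 4, 1, seed = 9)   # 100 samples balanced
  sp <- holdout_split(coh, 0.2, seed = 3)
  expect_equal(length(sp$test$labels), 20)
  expect_equal(sum(sp$test$labels == 1L), 10)
  sp2 <- holdout_split(coh, 0.2, seed = 3)
  expect_identical(sp$test$values, sp2$test$values)
  # dev and test partition the cohort
  expect_equal(length(sp$dev$labels) + length(sp$test$labels), 100)
  all_rows <- rbind(sp$dev$values, sp$test$values)
  expect_equal(nrow(unique(rbind(all_rows, coh$values))), 100)
  expect_error(holdout_split(planted_cohort(2, 3, 1, seed = 1), 0.2,
                             seed = 1), "too small")
})

test_that("repeated CV reports repetition-level mean/SD and reproduces under a fixed seed", {
  coh <- planted_cohort(60, 5, 2, shift_sd = 1.5, seed = 13)
  ctrl <- wdd_control(epochs = 40)
  cv1 <- repeated_cv(coh, variant = "di", control = ctrl, k = 3,
                     repetitions = 1, seed = 2)
  expect_true(all(cv1$summary$sd == 0))
  expect_true(all(cv1$summary$mean >= 0 & cv1$summary$mean <= 1))
  cv2 <- repeated_cv(coh, variant = "di", control = ctrl, k = 3,
                     repetitions = 3, seed = 2)
  cv3 <- repeated_cv(coh, variant = "di", control = ctrl, k = 3,
                     repetitions = 3, seed = 2)
  expect_identical(cv2$per_repetition, cv3$per_repetition)
  expect_error(repeated_cv(subset_cohort(coh, c(1, 61:70)), k = 10),
               "fewer samples")
})

test_that("the protocol harness fixes one test split and reports all variants", {
  coh <- planted_cohort(80, 5, 2, shift_sd = 1.5, seed = 17)
  pr <- screening_protocol(coh, variants = c("di", "bf"), k = 3,
                           repetitions = 2, seed = 4,
                           control = wdd_control(epochs = 40))
  expect_setequal(unique(pr$table$variant), c("di", "bf"))
  expect_equal(nrow(pr$table), 10)  # 2 variants x 5 metrics
  expect_true(all(pr$table$cv_mean >= 0 & pr$table$cv_mean <= 1))
  expect_true(all(pr$table$independent >= 0 & pr$table$independent <= 1))
  expect_equal(length(pr$split$test$labels), 32)
})

test_that("group construction: 26 groups under the 8-age x 2-sex configuration", {
  coh <- planted_cohort(400, 4, 2, shift_sd = 2, seed = 23)
  coh$age <- runif(800, 5, 95)
  coh$sex <- rep(c("male", "female"), 400)
  groups <- group_spec(coh, n_age_bins = 8, mode = "all")
  expect_length(groups, 26)
  expect_length(group_spec(coh, n_age_bins = 1, mode = "sex"), 2)
  # every sample belongs to exactly 1 age group, 1 sex group, 1 cross group
  membership <- Reduce(`+`, group_spec(coh, 8, "all"))
  expect_true(all(membership == 3))
})

test_that("group models produce a column-normalized weight matrix and skip degenerate groups", {
  coh <- planted_cohort(300, 4, 2, shift_sd = 2, seed = 29)
  coh$age <- runif(600, 20, 60)
  coh$sex <- rep(c("male", "female"), 300)
  gm <- group_models(coh, variant = "di", n_age_bins = 2, mode = "all",
                     control = wdd_control(epochs = 40))
  expect_length(gm$models, 8)  # 2 age + 2 sex + 4 cross
  expect_equal(unname(colSums(gm$weights)), rep(1, 8), tolerance = 1e-12)
  # single-class group is skipped with a warning
  coh2 <- subset_cohort(coh, c(which(coh$labels == 1L & coh$sex == "male"),
                               which(coh$sex == "female")))
  expect_warning(gm2 <- group_models(coh2, variant = "di", n_age_bins = 1,
                                     mode = "sex",
                                     control = wdd_control(epochs = 30)),
                 "skipped")
  expect_length(gm2$models, 1)
})
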