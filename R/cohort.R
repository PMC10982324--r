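#' Reference feature profiles for a 43-indicator physical-examination panel
#'
#' Class-conditional marginal parameters (mean and SD per class) for the 43
#' routine physical-examination indicators used throughout the package's
#' synthetic cohorts: urinalysis, blood-cell analysis and biochemistry panels.
#' The positive class models a T2DM-like screening population, the negative
#' class a healthy-control population. The default per-feature missing rate is
#' 0.05 and can be edited on the returned data frame before simulation.
#'
#' @return A data frame with one row per indicator and columns `feature`,
#'   `unit`, `mean_neg`, `sd_neg` (control class), `mean_pos`, `sd_pos`
#'   (positive class) and `missing_rate`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' prof <- default_profiles()
#' nrow(prof)            # 43 indicators
#' prof[prof$feature == "TC", ]
default_profiles <- function() {
  tab <- c(
    "TC",        "mmol/L",   4.96,  0.932,    4.63,  1.393,
    "AST",       "U/L",     24.58, 12.877,   25.20, 37.516,
    "GFR",       "mL/min",  94.01, 14.660,   87.98, 29.298,
    "Crea",      "umol/L",  68.48, 20.157,   86.93, 80.094,
    "HDL-C",     "mmol/L",   1.40,  0.368,    1.14,  0.369,
    "TG",        "mmol/L",   1.61,  1.313,    2.28,  2.377,
    "LDL-C",     "mmol/L",   3.09,  0.900,    2.71,  1.014,
    "ALT",       "U/L",     24.78, 19.111,   26.82, 32.369,
    "GGT",       "U/L",     30.62, 40.086,   49.49, 110.088,
    "AST/ALT",   "ratio",    1.19,  0.547,    1.18,  0.969,
    "MUCUS",     "/uL",     12.88, 18.193,    2.75, 12.213,
    "BACT",      "/uL",     21.38, 366.085, 1998.54, 7639.814,
    "EC",        "/uL",      6.81, 25.506,    5.28, 14.011,
    "BLD",       "",         0.31,  0.628,    0.27,  0.603,
    "U-SG",      "",         1.02,  0.006,    1.02,  0.008,
    "U-pH",      "",         5.88,  0.729,    5.73,  0.719,
    "Crystal",   "/uL",      6.09, 37.158,   23.45, 178.737,
    "RBC-Urine", "/uL",      7.29, 165.853,  20.96, 267.325,
    "WBC-Urine", "/uL",     14.43, 140.372,  61.44, 640.552,
    "NEU",       "10E9/L",   3.64,  1.290,    5.50,  3.591,
    "NEU-R",     "%",       59.31,  8.511,   68.59, 11.639,
    "PCT",       "%",        0.22,  0.051,    0.24,  0.086,
    "PDW",       "%",       16.15,  1.010,   15.48,  2.733,
    "PLT",       "10E9/L", 210.83, 56.276,  206.96, 80.247,
    "MPV",       "fL",      10.74,  1.412,   11.44,  1.400,
    "HGB",       "g/L",    142.27, 15.014,  126.97, 21.740,
    "EOS",       "10E9/L",   0.16,  0.161,    0.13,  0.172,
    "EOS-R",     "%",        2.62,  2.317,    1.99,  2.336,
    "BASO",      "10E9/L",   0.03,  0.018,    0.02,  0.020,
    "BASO-R",    "%",        0.53,  0.283,    0.24,  0.258,
    "LYM",       "10E9/L",   1.88,  0.617,    1.57,  0.665,
    "LYM-R",     "%",       31.65,  7.991,   23.10, 10.179,
    "HCT",       "",         0.44,  0.041,    0.39,  0.063,
    "RDW-SD",    "fL",      43.18,  2.994,   42.91,  4.282,
    "RDW-CV",    "%",       13.15,  0.975,   13.34,  1.305,
    "RBC",       "10E12/L",  4.66,  0.489,    4.33,  0.732,
    "MCHC",      "g/L",    325.53,  8.441,  328.30, 14.113,
    "MCH",       "pg",      30.62,  2.417,   29.40,  2.533,
    "MCV",       "fL",      94.00,  6.445,   89.55,  6.784,
    "MONO",      "10E9/L",   0.35,  0.122,    0.45,  0.257,
    "MONO-R",    "%",        5.88,  1.491,    6.12,  2.300,
    "P-LCR",     "",        31.37,  9.845,   36.20, 10.018,
    "WBC",       "10E9/L",   6.08,  2.075,    7.68,  3.860)
  m <- matrix(tab, ncol = 6, byrow = TRUE)
  data.frame(
    feature      = m[, 1],
    unit         = m[, 2],
    mean_neg     = as.numeric(m[, 3]),
    sd_neg       = as.numeric(m[, 4]),
    mean_pos     = as.numeric(m[, 5]),
    sd_pos       = as.numeric(m[, 6]),
    missing_rate = 0.05,
    stringsAsFactors = FALSE)
}

validate_profiles <- function(profiles) {
  need <- c("feature", "mean_neg", "sd_neg", "mean_pos", "sd_pos",
            "missing_rate")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stopf("profiles is missing column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(profiles)) stopf("profiles must contain at least one feature")
  if (any(profiles$sd_neg <= 0) || any(profiles$sd_pos <= 0))
    stopf("profile SDs must be strictly positive")
  if (any(profiles$missing_rate < 0 | profiles$missing_rate > 1))
    stopf("missing_rate must lie in [0, 1]")
  if (anyDuplicated(profiles$feature))
    stopf("duplicate feature names in profiles")
  profiles
}

#' Construct a cohort object
#'
#' A `wdd_cohort` bundles a samples-by-features numeric matrix (with `NA`
#' marking missing entries), binary labels (1 = positive/case), and optional
#' age and sex covariates. All modelling and evaluation functions in the
#' package operate on this container.
#'
#' @param values Numeric matrix, samples in rows, features in columns. `NA`
#'   entries are treated as missing. Column names are used as feature names.
#' @param labels Vector of 0/1 labels, one per row of `values`.
#' @param age Optional numeric vector of ages in years.
#' @param sex Optional character/factor vector with levels `male`/`female`.
#' @param feature_names Optional character vector overriding column names.
#' @return An object of class `wdd_cohort`: a list with elements `values`,
#'   `labels`, `feature_names`, `age`, `sex`.
#' @export
wdd_cohort <- function(values, labels, age = NULL, sex = NULL,
                       feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  labels <- as.integer(labels)
  if (length(labels) != n)
    stopf("labels length (%d) != number of samples (%d)", length(labels), n)
  if (!all(labels %in% c(0L, 1L)))
    stopf("labels must contain only 0 and 1")
  fn <- feature_names %||% colnames(values) %||%
    sprintf("feat_%02d", seq_len(ncol(values)))
  if (length(fn) != ncol(values))
    stopf("feature_names length != number of features")
  colnames(values) <- fn
  if (!is.null(age) && length(age) != n) stopf("age length != sample count")
  if (!is.null(sex)) {
    if (length(sex) != n) stopf("sex length != sample count")
    sex <- as.character(sex)
    bad <- setdiff(unique(sex[!is.na(sex)]), c("male", "female"))
    if (length(bad)) stopf("sex values must be 'male'/'female', got: %s",
                           paste(bad, collapse = ", "))
  }
  structure(list(values = values, labels = labels, feature_names = fn,
                 age = age, sex = sex),
            class = "wdd_cohort")
}

#' @export
print.wdd_cohort <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<wdd_cohort> %d samples x %d features\n", n, ncol(x$values)))
  cat(sprintf("  positives: %d, negatives: %d\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!is.null(x$age)) cat(sprintf("  age: %.0f-%.0f years\n",
                                   min(x$age), max(x$age)))
  if (!is.null(x$sex)) cat(sprintf("  sex: %d male / %d female\n",
                                   sum(x$sex == "male"),
                                   sum(x$sex == "female")))
  inf <- attr(x, "informative")
  if (!is.null(inf))
    cat("  planted informative features:", paste(inf, collapse = ", "), "\n")
  invisible(x)
}

#' Observed-value mask of a cohort
#'
#' @param cohort A `wdd_cohort`.
#' @return Logical matrix, `TRUE` where the entry is observed.
#' @export
cohort_mask <- function(cohort) !is.na(cohort$values)

#' Subset a cohort by sample index
#'
#' @param cohort A `wdd_cohort`.
#' @param idx Integer or logical index over samples.
#' @return A `wdd_cohort` containing the selected samples.
#' @export
subset_cohort <- function(cohort, idx) {
  out <- wdd_cohort(cohort$values[idx, , drop = FALSE],
                    cohort$labels[idx],
                    age = cohort$age[idx],
                    sex = cohort$sex[idx],
                    feature_names = cohort$feature_names)
  attr(out, "informative") <- attr(cohort, "informative")
  out
}

#' Simulate a synthetic screening cohort
#'
#' Draws a two-class cohort whose per-feature class-conditional marginals are
#' Gaussian with the means and SDs given in `profiles` (by default the
#' 43-indicator panel of [default_profiles()]). Entries are masked missing
#' completely at random at each feature's `missing_rate`; age is uniform over
#' `age_range` and sex Bernoulli(`prop_male`), both independent of class.
#' Marginals are independent by default; a correlation matrix induces
#' dependence through a Gaussian copula applied within each class.
#'
#' Draws are not truncated: physically nonnegative indicators may receive
#' negative values, which is harmless downstream because features are
#' normalized before modelling and keeps the Gaussian sampling theory exact.
#'
#' @param n_pos,n_neg Number of positive / negative samples.
#' @param profiles Data frame as returned by [default_profiles()].
#' @param age_range Length-2 numeric, years.
#' @param prop_male Probability a sample is male.
#' @param corr Optional feature correlation matrix (Gaussian copula); default
#'   identity (independent features).
#' @param seed Integer seed; equal seeds give bit-identical cohorts. `NULL`
#'   uses the current RNG state.
#' @param allow_single_class Permit `n_pos` or `n_neg` of 0 (for downstream
#'   error-path testing only).
#' @return A [wdd_cohort()].
#' @export
#' @examples
#' coh <- simulate_cohort(100, 100, seed = 1)
#' coh
simulate_cohort <- function(n_pos, n_neg, profiles = default_profiles(),
                            age_range = c(5, 95), prop_male = 0.5,
                            corr = NULL, seed = NULL,
                            allow_single_class = FALSE) {
  profiles <- validate_profiles(profiles)
  if ((n_pos == 0 || n_neg == 0) && !allow_single_class)
    stopf("single-class cohorts require allow_single_class = TRUE")
  if (n_pos + n_neg < 2) stopf("need at least 2 samples")
  if (age_range[1] >= age_range[2]) stopf("age_range must be increasing")
  f <- nrow(profiles)
  gen <- function() {
    draw_class <- function(n, mu, sd) {
      z <- matrix(stats::rnorm(n * f), n, f)
      if (!is.null(corr)) z <- z %*% chol(corr)
      sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
    }
    vp <- draw_class(n_pos, profiles$mean_pos, profiles$sd_pos)
    vn <- draw_class(n_neg, profiles$mean_neg, profiles$sd_neg)
    values <- rbind(vp, vn)
    n <- n_pos + n_neg
    u <- matrix(stats::runif(n * f), n, f)
    values[u < rep(profiles$missing_rate, each = n)] <- NA_real_
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- ifelse(stats::runif(n) < prop_male, "male", "female")
    wdd_cohort(values, c(rep(1L, n_pos), rep(0L, n_neg)),
               age = age, sex = sex, feature_names = profiles$feature)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a planted-signal cohort
#'
#' Generates a two-class cohort in which `f_informative` features carry a
#' class-mean shift of `shift_sd` standard deviations while the remaining
#' features are identically distributed noise in both classes. Used as a
#' ground-truth fixture for signal-recovery and null-behaviour checks. The
#' indices of the informative features are stored in the `"informative"`
#' attribute of the returned cohort.
#'
#' @param n_per_class Samples per class.
#' @param f_total Total features.
#' @param f_informative Number of shifted features (the first
#'   `f_informative` columns).
#' @param shift_sd Class-mean separation in SD units; 0 gives exchangeable
#'   classes (null case).
#' @param missing_rate MCAR missingness probability applied uniformly.
#' @param seed Integer seed or `NULL`.
#' @return A [wdd_cohort()] with attribute `informative`.
#' @export
planted_cohort <- function(n_per_class, f_total, f_informative,
                           shift_sd = 1.5, missing_rate = 0, seed = NULL) {
  if (f_informative > f_total) stopf("f_informative must be <= f_total")
  if (shift_sd < 0) stopf("shift_sd must be >= 0")
  gen <- function() {
    n <- 2L * n_per_class
    values <- matrix(stats::rnorm(n * f_total), n, f_total)
    if (f_informative > 0)
      values[seq_len(n_per_class), seq_len(f_informative)] <-
        values[seq_len(n_per_class), seq_len(f_informative)] + shift_sd
    if (missing_rate > 0) {
      u <- matrix(stats::runif(n * f_total), n, f_total)
      values[u < missing_rate] <- NA_real_
    }
    colnames(values) <- sprintf("feat_%02d", seq_len(f_total))
    out <- wdd_cohort(values,
                      c(rep(1L, n_per_class), rep(0L, n_per_class)))
    attr(out, "informative") <- seq_len(f_informative)
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
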