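---
title: "Weighted diversity density models for clinical screening: methods and design"
author: "wddscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted diversity density models for clinical screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wddscreen)
```

## The model

Binary screening on routine clinical indicators is often done with black-box
learners whose decisions are hard to audit. The weighted diversity density
(WDD) family takes the opposite route: it learns a single *prototype point*
$x = (x_1, \dots, x_f)$ in normalized feature space together with
nonnegative per-feature weights $s = (s_1, \dots, s_f)$, and scores a sample
$b_i$ by its weighted squared distance to the prototype,

$$\mathrm{Dist}(b_i, x) = \sum_k \mathrm{Dist}_k, \qquad
  \mathrm{Dist}_k = s_k (b_{ik} - x_k)^2 .$$

The prototype is chosen to maximize the probability density of positive
(case) samples near $x$ while minimizing that of negative (control)
samples, via

$$\Pr(+\,|\,b_i) = \exp(-\gamma\,\mathrm{Dist}(b_i, x)), \qquad
  \Pr(-\,|\,b_i) = 1 - \exp(-\gamma\,\mathrm{Dist}(b_i, x)),$$

and the joint negative log-likelihood
$-\sum_{i \in +} \log \Pr(+\,|\,b_i) - \sum_{i \in -} \log \Pr(-\,|\,b_i)$
is minimized over $(x, s)$ by full-batch Adam. Because the score
decomposes feature-wise into the $\mathrm{Dist}_k$, and because the
learned $s_k$ directly measure how much each indicator contributes to the
decision, the model is interpretable without third-party attribution
tools: `weight_report()` and `group_distk_summary()` read the explanation
straight off the parameters.

### The three variants

* **KNN** (`variant = "knn"`): missing entries are imputed before fitting
  (k-nearest-neighbour donor means, $k = 15$); the distance above is used
  unchanged. Prediction for incomplete samples requires an imputation
  reference, which the in-memory model keeps (`keep_data = TRUE`); a model
  file reloaded from JSON does not, and refuses incomplete inputs.
* **DI** (`variant = "di"`): missing features contribute zero to the sum and
  the distance is divided by $(f - f_{\mathrm{miss}})^{\delta}$. This
  *shrinks* the diversity density of samples with many missing values, so
  the optimum depends less on low-quality records. A sample with every
  feature missing has no defined score and is rejected with an error.
* **BF** (`variant = "bf"`): each observed feature contributes a bounded
  similarity term $\mathrm{Dist}'_k = \exp(-\gamma s_k |b_{ik} - x_k|)$
  (zero when missing), aggregated as
  $\mathrm{Dist}' = \sum_k (\mathrm{Dist}'_k)^{\lambda}$ with
  $\Pr(+) = 1 - \exp(-\mathrm{Dist}')$ and $\Pr(-) = \exp(-\mathrm{Dist}')$.
  Missing features are simply ignored; an all-missing sample scores 0 with
  $\Pr(+) = 0$.

Two printed ambiguities in the BF family required a reading to be fixed.
First, we read the aggregation exponent per term,
$\sum_k (\mathrm{Dist}'_k)^\lambda$; an outer exponent
$(\sum_k \mathrm{Dist}'_k)^\lambda$ differs only by a strictly monotone
transform of the score, which leaves the ROC curve, AUC, and Youden ranking
unchanged, so we provide only the per-term form. Second, the BF probability
pair is defined directly as $1 - \exp(-\mathrm{Dist}')$ /
$\exp(-\mathrm{Dist}')$, the only composition that keeps the intended
monotonicity (more observed similarity means higher positive probability)
and keeps both values in $[0, 1]$.

### Risk scores and thresholds

For the KNN and DI variants the reported risk score is the diversity
density $\exp(-\gamma \cdot \text{penalized distance}) \in (0, 1]$; for BF
it is the raw similarity $\mathrm{Dist}'$, which is unbounded above (it can
exceed 1, matching its different dynamic range). The decision threshold is
selected on the training scores by maximizing Youden's $J =$ TPR $-$ FPR
over all observed cutoffs, with ties broken toward the smallest qualifying
cutoff (maximal sensitivity at equal $J$); the classification rule is
`score >= threshold`.

## Preprocessing

Three steps precede fitting, mirroring routine EHR practice:

1. **Robust normalization with outlier nulling.** Per feature, Q1/Q3 are
   computed over observed values with linear-interpolation quantiles
   (R's default `type = 7`; the convention matters because the Tukey fences
   $[Q1 - 1.5\,\mathrm{IQR},\, Q3 + 1.5\,\mathrm{IQR}]$ depend on it, so it
   is fixed and documented). Values outside the fences are *set to missing*,
   and $\mu_j, \sigma_j$ (sample SD, $n-1$ denominator) are estimated from
   the in-fence observed values; features with $\sigma_j = 0$ are dropped.
   Remaining values become $(x - \mu_j)/\sigma_j$.
2. **Imputation (KNN variant only).** Missing-aware Euclidean distances
   (mean squared difference over mutually observed coordinates, rescaled to
   full dimension) rank donors; each missing cell takes the unweighted mean
   of the $k = 15$ nearest donors observing that feature, clamped to the
   available donors. The imputed matrix is then re-normalized by a fresh
   fit-and-apply pass *without* outlier nulling: re-nulling after imputation
   would re-create missingness and could oscillate.
3. **Class-missingness equalization (DI/BF only).** Per feature, the class
   with the lower missing rate has observed entries randomly masked
   (seeded) until the per-class missing rates agree to integer resolution.
   This removes label-informative missingness that the
   missing-value-tolerant scores would otherwise exploit as a shortcut.
   Entries are only ever masked, never restored. The exact balancing
   mechanism used in the original study is not publicly specified;
   masking-to-equalize is our reading, chosen because it is conservative
   (it can only remove information).

Normalization statistics are always fitted on training data only and applied
to held-out data. In cross-validation this happens per fold; equalization is
likewise applied to training folds only, since it is a fitting-bias control,
not a measurement correction.

## Optimization and numerics

* Nonnegativity of $s$ is enforced by the softplus reparameterization
  $s_k = \log(1 + e^{r_k})$; the raw parameters are unconstrained. Negative
  weights would break $\Pr \in [0, 1]$.
* The prototype initializes at the per-feature mean of positive-class
  observed values (`init_x = "pos_mean"`); weights initialize at
  $s_k = 1$. Both choices make the initial loss finite on standardized
  data.
* Optimizer defaults: Adam, learning rate 0.05, 500 epochs, $\beta =
  (0.9, 0.999)$, $\varepsilon = 10^{-8}$, full-batch gradients (the cohorts
  are small by deep-learning standards). The returned model carries the
  best-loss parameters seen, so the stored loss trajectory is
  non-increasing. An optional relative-improvement tolerance
  (`convergence_tol`) stops early; it is off by default.
* The likelihood is computed in log space. Terms with an exact log form
  ($-\log e^{-a} = a$) are evaluated directly and never floored — this
  matters: on 43-feature cohorts the initial distances can exceed 50, where
  $e^{-a}$ underflows past any floor, and flooring such terms would place
  the optimizer on a flat plateau with zero gradient, silently preventing
  training. Terms of the form $-\log(1 - e^{-a})$, which genuinely diverge
  as $a \to 0$, have the probability floored at $10^{-12}$ before the
  logarithm ($1 - e^{-a}$ itself is computed as `-expm1(-a)`); floored
  samples contribute zero gradient, keeping the analytic gradient
  consistent with finite differences of the actual loss — the test suite
  verifies agreement to $10^{-4}$ relative error at $h = 10^{-5}$.
* Given the data and configuration, fitting is fully deterministic: no
  stochastic minibatching, no random initialization. Randomness enters only
  through data generation, splits, fold shuffles, and the equalization
  masking, all of which are seeded.
* Hyperparameter defaults are $\gamma = \delta = \lambda = 1$. The original
  study's tuned values are not public; `wdd_tune()` provides a small
  held-out grid search. One scale effect matters in practice: the raw
  KNN-variant distance grows linearly with the feature count, so on wide
  panels $\gamma = 1$ puts the exponential probabilities in a badly
  calibrated regime and $\gamma$ of order $1/f$ is appropriate — the DI
  variant is nearly scale-free here because its $(f -
  f_{\mathrm{miss}})^\delta$ division performs exactly that rescaling, and
  BF is bounded per feature by construction. The acceptance script
  therefore selects $\gamma$ per variant over the grid $\{1, 1/\sqrt{f},
  1/f\}$ on the development set before running the protocol.

## The synthetic cohort generator

No clinical records ship with the package. `simulate_cohort()` draws
cohorts whose 43 per-feature class-conditional marginals (means and SDs for
a screening-positive and a control population over routine urinalysis,
blood-cell and biochemistry indicators) match the published summary table
bundled as `default_profiles()`. Design choices:

* **Independent Gaussian marginals.** Only means and SDs are published; no
  covariance is available. A Gaussian-copula hook (`corr =`) lets users
  impose a correlation structure, but the default is identity so that the
  sampling theory behind the generator tests stays exact.
* **Uniform 5% MCAR missingness** per feature by default. Real screening
  cohorts have indicator-specific missing rates, but no per-indicator set
  is published alongside the summary statistics; the rate is a per-feature
  column in the profile table and fully configurable.
* **No truncation** of physically nonnegative indicators: normalization
  makes the scale irrelevant downstream, and truncation would invalidate
  the closed-form Gaussian checks used in the tests.
* Age is uniform over 5–95 years and sex Bernoulli(0.5), independent of
  class — adequate for exercising the grouping machinery, though real
  cohorts have age- and sex-dependent prevalence.

`planted_cohort()` generates ground-truth fixtures: a chosen number of
informative features with a class-mean shift in SD units, the rest
exchangeable noise. What passing the planted-signal tests shows is that the
pipeline recovers separations of known geometry under MCAR missingness; it
does not show robustness to correlated indicators, informative
missingness, covariate shift, or label noise, all of which real EHR data
exhibit.

## Evaluation protocol

`screening_protocol()` reproduces the benchmark design at desk scale: a
stratified 8:2 development/independent-test split fixed once per seed,
then repeated stratified 10-fold cross-validation on the development set.
Metrics (AUC by rank statistics with the tie-as-half convention, accuracy,
precision, recall, F1; precision and F1 defined as 0 when nothing is
predicted positive) are computed per fold at the fold-model's Youden
threshold, averaged within a repetition, and summarized as mean (SD)
across repetitions. Stratification is used for both the split and the
folds — without it, small subgroups would routinely produce single-class
folds. The repetition-level SD convention was adopted because the
benchmark's "mean (SD) of repetitions" phrasing is ambiguous between fold-
and repetition-level spread.

Because fitting is deterministic, the fixed independent test produces
identical numbers every repetition; the protocol therefore evaluates it
once per variant. A nonzero SD on a fixed test set is only possible with
stochastic training, which this implementation deliberately avoids.

Default problem sizes are chosen for interactive use: 10 repetitions
(1000 in the original protocol is supported but is a cluster-scale run),
cohorts of 1600 samples for the protocol checks, and 150-epoch
convergence-tolerant fits inside the repeated-CV harnesses, which on this
model family reach the same ranking as full 500-epoch fits. The package's
acceptance script states the sizes it uses alongside each number it
reports.

`group_models()` fits one model per demographic subgroup — by default 8
contiguous age bins spanning the observed age range, 2 sexes, and the 16
age-by-sex crosses, 26 groups in all — and assembles the features-by-groups
matrix of normalized weights (each column sums to 1), the heatmap used to
compare which indicators matter for which subpopulation. The original
study's exact bin edges are unpublished; equal-width bins over the observed
range are the default and are configurable. Groups that lose a class (or
fall below `min_per_class`) are skipped with an explicit warning, never
silently.

## Interpretability conventions

* Normalized weights are $s / \sum_k s_k$, computed from the *effective*
  (post-softplus) weights; the normalization is invariant to positive
  rescaling of $s$.
* "Important features" are the top $\lceil 0.25 f \rceil$ by normalized
  weight (for $f = 43$: 11 features). Ceiling rounding was chosen so the
  rule never returns an empty set; ties break by input feature order,
  making ranks stable and reproducible.
* `consensus_features()` intersects top sets across models (at least
  `min_models` of them), the cross-algorithm agreement rule used to nominate
  robust indicators.
* The univariate screen `feature_difference_test()` is a two-sided
  Mann-Whitney U via `stats::wilcox.test` (normal approximation with tie and
  continuity correction); the tests validate its U statistic against direct
  pairwise counting.

## Known limitations

* Independent-marginal synthetic cohorts are easier than real EHR data;
  reported synthetic AUCs should not be read as clinical performance.
* The DI penalty makes scores incomparable across samples with different
  missingness counts by design; risk-score *distributions* should be
  compared within missingness strata when that matters.
* BF weight rankings are not directly comparable to KNN/DI rankings: in the
  bounded-similarity geometry a large weight suppresses a feature's
  similarity term rather than amplifying a distance, so cross-variant
  consensus is most meaningful between KNN and DI.
* KNN-variant model files are not self-contained for incomplete inputs —
  an imputation reference is required at prediction time. This is the main
  practical argument for the DI/BF variants.

## A worked example

```{r example}
coh <- planted_cohort(300, 12, 3, shift_sd = 1.5, missing_rate = 0.05,
                      seed = 1)
sp <- holdout_split(coh, 0.2, seed = 1)
fit <- wdd(sp$dev, variant = "di", control = wdd_control(epochs = 200))
fit
roc_auc(predict(fit, sp$test), sp$test$labels)
names(top_fraction_features(fit, 0.25))
```
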