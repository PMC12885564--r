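---
title: "Consensus feature importance with WIS and FC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus feature importance with WIS and FC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wisfc)
```

## The problem

Train five reasonable models on the same small tabular dataset — a logistic
regression, a decision tree, a random forest, a gradient boosting machine and
a kernel SVM — and ask each which features matter. They will disagree,
often substantially. On small datasets (a few hundred rows, dozens of
candidate predictors, as is typical of clinical cohorts) each model latches
onto a different subset of correlated weak signals, and any single model's
importance ranking is an unreliable basis for scientific claims. The naive
remedies are both bad: picking the best-performing model's ranking inherits
that model's instability, and intersecting top-k lists discards genuinely
informative features on which the models merely *partially* agree.

This package aggregates the rankings instead, scoring every feature on two
complementary axes:

* **Weighted Importance Score (WIS)** — strength. Each model's raw
  importances are normalized onto a comparable scale; the WIS of feature
  $f$ is the weighted sum $\mathrm{WIS}(f) = \sum_{j=1}^{N} w_j R_j(f)$
  across the $N$ models. With rank normalization and equal weights this is
  the feature's mean rank (lower is better).
* **Frequency Count (FC)** — consistency. The number (or fraction) of
  models placing $f$ within their top-$k$ importance list. FC is a plain
  vote: one model, one count, regardless of the WIS weights.

A feature with extreme importance in one model but ignored by the rest gets
a mediocre WIS (its lone vote is diluted by $N-1$ poor ranks) and a low FC —
exactly the cautionary signal a practitioner needs. A feature that is never
anyone's top pick but ranks 3rd–6th everywhere gets a good WIS and a perfect
FC, and is promoted rather than discarded.

## Normalization

Raw importances are not comparable across model families (absolute logistic
coefficients, impurity reductions and permutation drops live on different
scales), so each model's output is normalized **per model, column-wise**,
never globally:

* **rank** (default): importances become ranks $1..p$, 1 = most important.
  Ties get the average of the ranks they span, so the transform never
  depends on input order. Ranks are robust to heavy-tailed importance
  distributions, which is why they are the default.
* **sum**: importances are divided by their per-model sum, giving relative
  shares in $[0,1]$ that sum to 1. Shares retain magnitude information that
  ranks discard, at the cost of sensitivity to outlying values.

Signed metrics (regression coefficients) enter as magnitudes; tracking sign
agreement across models is a deliberate non-goal.

When models report different feature sets, the union of features forms the
matrix rows and the absent cells must be filled. The default policy
(`fill = "worst"`) assigns the worst rank (the pool size) or share 0: a
model that never surfaces a feature is treated as evidence against it, in
the same spirit in which absence from a top-$k$ list is a non-vote in FC.
The alternative (`fill = "exclude"`) leaves the cell missing and
renormalizes the model weights per feature over the models that did report
it — appropriate when models genuinely saw different candidate pools rather
than declining to rank a feature.

## Model weights

By default every model's opinion counts equally ($w_j = 1/N$). When there is
reason to trust some models more, weights can be made proportional to
validation performance through a softmax:

$$ w_j = \frac{e^{\mathrm{perf}_j / T}}{\sum_{k=1}^{N} e^{\mathrm{perf}_k / T}} $$

Weights are positive, sum to 1, are invariant to adding a constant to all
performances, and preserve performance order. The temperature $T$ (default
1, the plain softmax) is exposed because performance scales differ:
accuracies of 0.79 vs 0.81 give nearly equal weights at $T = 1$, while
$R^2$ values spanning 0.3–0.9 give sharply unequal ones; $T$ makes that
trade-off an explicit choice rather than an accident of the metric. Two
cautions, enforced by documentation rather than heuristics: performances
must be **held-out** scores (the harness only ever reports fold-averaged
cross-validation performance — weighting by training fit would systematically
overweight the most overfit model), and lower-is-better metrics must be
negated by the caller.

## Combining the two axes

* **Joint criteria** (`selected` column): a feature is flagged robust when
  `fc_fraction >= fc_threshold` (default 0.5: at least half the models) *and*
  its WIS reaches the best `wis_quantile` of all candidates (default 0.25:
  top quartile). The quantile boundary uses the nearest-rank convention and
  is inclusive, so exact ties at the cut are selected — no silent dropping
  of boundary features.
* **Composite score**: $C(f) = \mathrm{WIS}(f) \cdot \mathrm{FC}(f)/N$.
  The product only *penalizes* inconsistency when WIS is oriented
  higher-is-better, so rank-based WIS must first be inverted through the
  order-reversing affine map $p + 1 - \mathrm{WIS}$ (best mean rank 1
  becomes $p$, worst becomes 1). `composite_score()` refuses rank-oriented
  input outright: mixing orientations silently would reward exactly the
  features the composite is meant to demote.
* **Final ranking**: sort by WIS (best first), break ties by higher FC, and
  break remaining exact ties lexicographically by feature name. The last
  rule has no scientific content; it exists so the ranking is a
  reproducible total order.
* **Interpretation categories**: crossing WIS strength (top quartile by
  default) with FC consistency (≥ 50% by default) yields `ROBUST`
  (report with confidence), `MODEL_SPECIFIC` (strong but uncorroborated —
  investigate before trusting), `CONSISTENT_MODERATE` (never a top pick but
  corroborated everywhere — follow up), and `LOW_SIGNAL`.

## Choosing k

`k` controls what "appearing" in a model's list means. Too small, and valid
features hovering just outside the cutoff lose votes; too large, and FC
saturates at $N$ for everything and loses discrimination (FC is monotone in
`k` and equals $N$ for every feature once `k` reaches the pool size). The
default `k = 10` suits candidate pools of a few dozen features with roughly
ten plausibly relevant ones. `fc_sweep()` reports FC across several `k`
(default 3, 5, 10, 15): truly robust features keep a high FC across the
reasonable range, and a feature whose FC collapses when `k` shrinks was
barely making the lists.

A two-feature illustration of why both axes are needed: across five models,
Blood Pressure holds ranks [1, 2, 4, 1, 3] and Cholesterol [1, 8, 2, 15, 1]
(a slice of a 20-predictor pool). Both are "majority-selected" by any naive
top-k overlap, but WIS separates them — 2.2 vs 5.4 — and at `k = 10` FC is
5/5 vs 4/5: Blood Pressure never falls below fourth place, Cholesterol
crashes to 15th in one model.

```{r worked}
res <- wisfc(worked_example_matrix())
res
```

## The model harness

`run_harness()` implements the brute-force strategy the aggregation is
designed for: fit a deliberately diverse suite on one dataset and harvest
one importance vector per model. The default suite spans linear
(logistic/linear regression, absolute standardized coefficients), single
tree (rpart, impurity), bagged trees (ranger random forest, impurity),
boosted trees (xgboost, gain) and kernel methods (radial SVM, permutation
importance — the model-agnostic backend used where no native importance
exists; externally computed attributions such as SHAP tables can be supplied
instead through the standard importance CSV). Ensembles of near-identical
models add little information; diversity of inductive bias is what makes
the consensus meaningful.

Two design choices deserve note. Reported importances come from a refit on
the full dataset (the most data-efficient fit), while performance comes
exclusively from held-out folds of repeated cross-validation — the two
quantities serve different purposes and are deliberately computed on
different fits. And every source of randomness (fold assignment,
forest/boosting seeds, permutation draws) flows from declared seeds, so a
fixed (data, specs, seed) triple reproduces identical output to the byte.

## The synthetic benchmark

Real clinical registry data of the kind that motivates this package cannot
be redistributed, so validation uses `generate_cohort()`: $n$ rows of
standard-normal features (optionally in equicorrelated blocks of
within-block correlation $\rho$, single-factor construction, margins
N(0,1)), $s$ planted informative features with effect sizes spaced across
`beta_range`, and a linear-Gaussian or logistic-Bernoulli outcome. Defaults
(n = 300, p = 20, s = 5, effects 0.5–1.5 per SD, binary outcome) mirror the
small-cohort regime: strong enough that the signal is recoverable, weak
enough that no single model recovers it reliably — the regime where
aggregation has something to contribute.

What the generator does *not* emulate: realistic clinical covariate
distributions (skewed labs, categorical comorbidities), missingness,
nonlinear or interaction effects, and outcome imbalance. Passing recovery
tests therefore demonstrates correct aggregation arithmetic and the
directional benefit of consensus under an idealized linear signal, not
performance on real registry data.

Two validation experiments ship as package functions (both used by the test
suite and the acceptance script, at the sizes stated here — 20 seeds /
20 bootstrap resamples, harness CV 3-fold × 1):

* `recovery_experiment()` — planted-feature recovery: across independent
  cohorts, the consensus top-5 contains on average ≥ 4 of the 5 planted
  features and strictly more than the worst single model's top-5 (typically
  the decision tree, whose greedy splits make its importance list the most
  volatile).
* `stability_experiment()` — bootstrap stability: over B row-bootstrap
  resamples (every method scored on the identical resample sequence), the
  mean pairwise Jaccard similarity of the consensus top-5 sets is at least
  that of every single model. The margin over the *best* single model
  (usually the random forest, itself an internally averaged ensemble) is
  small and can invert on individual benchmark draws; the claim asserted and
  tested is direction on the fixed default benchmark, not an effect size.

The bootstrap-of-rows scheme was chosen over CV-fold perturbation because it
resamples the whole pipeline (fitting *and* importance extraction) and keeps
the sample size constant across resamples; mean pairwise Jaccard was chosen
as the stability metric because it is the standard set-overlap measure in
feature-selection stability work and needs no tuning beyond `k`.

```{r dilution}
# dilution: one model promotes f1 to rank 1, four models rank it worst;
# f5 holds a uniform mid-rank everywhere and beats f1 on WIS, while f1's
# low FC flags the lone strong vote
p <- 9
ranks <- sapply(1:5, function(j) {
  r <- numeric(p)
  if (j == 1) { r[1] <- 1; r[5] <- 5; r[-c(1, 5)] <- c(2:4, 6:9) }
  else        { r[1] <- 9; r[5] <- 5; r[-c(1, 5)] <- c(1:4, 6:8) }
  r
})
rownames(ranks) <- paste0("f", 1:p)
outs <- lapply(1:5, function(j)
  model_importance(paste0("m", j), ranks[, j], metric = "rank"))
res <- wisfc(outs, wisfc_config(k = 5))
res[res$feature %in% c("f1", "f5"), c("feature", "wis", "fc_fraction")]
```

## Numerical and degenerate-input choices

* Softmax weights subtract the maximum performance before exponentiating;
  shift-invariance then holds exactly, not just in theory.
* An all-zero importance vector is an error (`sum_scale` cannot scale it and
  an uninformative model should not silently contribute uniform shares).
* A single-model "ensemble" is an error: aggregation over one model is not
  an ensemble and returning its ranking unchanged would misrepresent what
  was computed.
* Pre-ranked inputs (metric `"rank"`) are preserved verbatim, and the
  implied candidate-pool size (the largest rank seen) is recorded so that
  inversion and worst-rank filling use the true pool, not the listed slice.
* Quantile gates use nearest-rank quantiles with inclusive boundaries;
  p = 4 features at `wis_quantile = 0.25` selects exactly the single best.
* `joint_select`, `categorize` and `composite_score` all require an explicit
  WIS orientation (carried as an attribute by the pipeline); no function
  guesses which direction "better" is.

## Limitations

* Correlated predictors split votes: when models alternate between
  correlated features, both end with moderate WIS and reduced FC even though
  the underlying signal is strong. Interpret feature *groups* in that case;
  clustering correlated features before aggregation is out of scope here.
* The consensus inherits shared biases: if every model sees the same flawed
  feature engineering, agreement is not evidence of truth.
* No confidence bounds are attached to WIS or FC values; the ranking is
  descriptive.
* FC is an unweighted vote even under softmax WIS weighting; a
  performance-weighted FC variant is deliberately not offered.
* Aggregation operates on global importances only; per-instance (local)
  explanation aggregation is out of scope.
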