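---
title: "Two-phase ensemble construction for HDLSS expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase ensemble construction for HDLSS expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itoensemble)
```

## The model

`itoensemble` addresses binary classification in the high-dimension,
low-sample-size (HDLSS) regime typical of expression data: a handful of
samples, thousands of features, class imbalance, and a small unknown subset
of truly class-informative features surrounded by correlated redundancy and
noise. No single classifier configuration generalises well across such
datasets, so the package embraces configuration diversity instead of fighting
it: many base models are trained under independently sampled pipeline
configurations, scored, filtered, and combined.

A base model's configuration is an *attack vector*
$(p, m, k, v)$: a preprocessing method $p$, a mutual-information
feature-selection criterion $m$, a subset size $k$, and a validation
protocol $v$. The full grid is the Cartesian product of the configured
option sets; each training wave samples half of it uniformly without
replacement (the `grid_fraction` default of 0.5).

Training proceeds in two waves. The first wave (LIG) uses parameter-free
classifiers — CART decision trees, discrete AdaBoost over depth-1 stumps,
and extremely randomized trees — so a serviceable ensemble is available
quickly; it is written to disk before the second wave begins, a contract the
test suite checks. The second wave (FT) uses parameterized classifiers —
random forest, SVM, and a single-hidden-layer perceptron — tuned by grid
search under the same selection protocol.

Each candidate is scored by the efficiency index
$$\rho = \mathrm{MCC} \times \mathrm{accuracy},$$
computed on pooled out-of-fold predictions under the attack vector's own
validation protocol. The product form is deliberate: in the overfitting
signature where accuracy rises while MCC falls, $\rho$ falls. Candidates
with $\mathrm{MCC} \le 0$ (no better than chance) are discarded outright;
the remainder must pass the strict fitness test $\rho > \epsilon$, with
$\epsilon$ chosen by `epsilon_for_fraction()` so that at least the top 33%
survive (ties at the boundary are all admitted), or supplied directly when
reproducing a known threshold.

Survivors are combined greedily, best $\rho$ first, under majority voting;
a tentative addition is kept only when the ensemble's $\rho$ on the
selection protocol does not deteriorate. The final ensemble pools both
waves' survivors, re-ranks, and rebuilds from scratch (strategy "c"); the
two rejected alternatives — the plain union of the wave ensembles ("a") and
growing one wave's ensemble with the other's members ("b") — are implemented
so the comparison is reproducible. Because the ensemble is seeded with the
top-ranked survivor and additions never lower $\rho$, the final ensemble's
selection-$\rho$ is at least the best individual soldier's; this is asserted
on every run. The stronger empirical pattern — the final ensemble also
dominating both wave *ensembles* — usually holds on synthetic runs but is
checked, not guaranteed: the greedy path from a merged pool need not
dominate a greedy path from either sub-pool.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `preps` | quantile, robust, standard, none | scaling options in the grid |
| `subset_sizes` | 10, 50, 100, 150, 200, 250 | features kept by selection |
| `fss_methods` | mrmr, jmi, jmim | greedy MI criteria |
| `validations` | tenfold_cv, loocv | selection protocols |
| `grid_fraction` | 0.5 | fraction of the grid sampled per wave |
| `fraction` | 0.33 | top fraction admitted by the ϵ filter |
| `epsilon_lig`, `epsilon_ft` | unset | explicit ϵ overrides |
| `n_bins` | 5 | equal-frequency bins for MI estimation |
| `final_strategy` | "c" | final-ensemble construction |
| `strict_improvement` | FALSE | require strictly increasing ρ |
| `max_features` | 5000 | width guard (bypass with `force = TRUE`) |

Subset sizes and option sets are dimensionless counts and names; the
efficiency index and its inputs live on their natural \[−1, 1\] / \[0, 1\]
scales.

## Numerical and design choices

**Preprocessing.** Features with any missing value in the *training* data
are removed everywhere — in the HDLSS regime features are abundant and a
probe that fails to cover the sample space is better dropped than imputed.
Residual missing cells on the validation side (within surviving features)
are imputed with the training median, so both halves of the rule coexist
without contradiction. Scalers are fit on the whole training set once per
attack vector, not refit per CV fold; this follows the pipeline order of the
two-wave algorithm and keeps soldier scores comparable across folds, at the
price of a mild optimistic bias in out-of-fold scores that we document
rather than hide (see the null-data limitation below). The quantile map
uses the empirical CDF convention $(\mathrm{rank}-0.5)/n$ with averaged
ranks for ties, interpolates linearly between training-value knots, and
clips new values outside the training range to \[0, 1\]. Constant features
transform to 0 (0.5 under quantile) instead of being dropped, keeping
feature indices aligned across attack vectors. All three scalers are
monotone per feature.

**Mutual information.** Features are equal-frequency discretized
(rank-then-bin, ties share a bin, constant vectors collapse to bin 0) into
5 bins by default — a standard small-sample choice; MI uses the plug-in
estimator in natural log. Only orderings matter for greedy selection, so
the log base is immaterial. mRMR uses the difference (MID) form
$I(X;Y) - \frac{1}{|S|}\sum_{s} I(X;X_s)$; JMI sums and JMIM minimizes
$I((X,X_s);Y)$ over the selected set, with joint variables on the product
alphabet of the two discretized features. Criterion ties — including values
that are mathematically equal but differ in floating-point summation order —
break toward the lower feature index within a $10^{-10}$ tolerance, making
selection fully deterministic.

**Determinism.** Every stage derives an independent 31-bit sub-seed from
the master seed (grid draws, fold assignment, per-soldier and per-candidate
fits). Classifier predictions are pure functions of (model, data): tied
tree votes in ranger and tied posterior columns in the perceptron are
resolved under a pinned RNG state rather than the session RNG. Two runs
with the same seed are bit-identical, across sessions.

**Grid-search adaptations.** The default FT grids keep the published 5×4×2
(SVM), 5×2×2 (random forest) and 8×3 (perceptron) shapes, adapted to the R
fitting engines: ranger's classification split rules are {gini, hellinger}
(no entropy criterion is available), `bootstrap = FALSE` maps to 0.632
subsampling without replacement, and nnet fits a single logistic hidden
layer, so the perceptron grid tunes weight decay (the eight alpha values)
and hidden width rather than activation or learning-rate schedules. Grid
ties break toward higher MCC, then first-seen grid order.

**Degenerate inputs.** A zero denominator in MCC (any empty confusion
marginal) yields 0, the chance-level convention. An improvement percentage
over a zero final score is reported as unavailable (`NA`). An empty
candidate list is an error for ensemble construction but an empty *LIG*
phase only warns, and the run continues on the second wave. Subset sizes
exceeding the surviving feature count clamp with a warning.

**Strategy "b" start.** The published description rejects strategy (b)
partly because starting from the higher-ρ wave ensemble admits nothing; the
implementation therefore starts from the lower-ρ ensemble and offers the
other's members, which is the variant whose shortfall the description
analyses.

## The synthetic generator

`generate_synthetic()` emulates the statistical shape of the benchmark
cohorts the method was developed against: far more features than samples,
two imbalanced classes, a small planted set of informative features
(Gaussian class-mean shift of `effect_size` within-class standard
deviations), noisy redundant copies of random informative features, and
missing values. Defaults are the benchmark-cohort shape — 70 training and
88 validation samples with a 26:44 positive:negative split, 500 features,
10 informative + 10 redundant, effect size 2, 5% missing cells in half the
noise features. Missing values land in noise features only (by default) so
the exclusion rule never destroys planted signal in recovery experiments; a
`missing_in = "anywhere"` switch exists for stress-testing the exclusion
rule itself.

The generator is intentionally simple: it does not simulate
platform-specific intensity distributions, probe effects, batch structure,
or heavy-tailed noise. Passing tests therefore demonstrate that the
machinery is correct and that the method behaves as designed on data with
planted Gaussian signal — not that any particular accuracy will be achieved
on real cohorts.

## Problem sizes used in the checks

The test suite exercises the oracle-equivalence study on fifty 30×8
datasets at $k = 3$; the planted-recovery study on fifty seeds at 100
samples × 500 features (10 + 10 planted, effect 2.0, top-10 selection); the
construction-guarantee study on one hundred seeded runs at 60 samples × 200
features; null-label studies on 150-sample datasets, where the
whole-training-set selection bias noted above is negligible (at 30 samples
it is visible — a deliberate illustration of why the bias is documented);
and end-to-end runs at the 70/88 benchmark shape. These sizes are the
package's chosen desk-scale study conditions; the method itself has no
intrinsic size limit beyond the `max_features` guard, which exists because
greedy MI selection over, say, a million features is a multi-day
computation.

## Known limitations

* Binary classification only; no multi-class generalisation of MCC or the
  vote rule.
* Majority voting over hard labels; soft/probability averaging, weighted
  votes and stacking are out of scope.
* The selection-ρ dominance guarantee is a statement about the data the
  greedy construction optimises against, not about holdout performance.
* FSS estimator settings (bins, log base) are configuration, not an
  equivalence claim against any other implementation's estimator.
* Whole-training-set scaler/FSS fitting leaks selection information into
  out-of-fold scores at very small $n$; scores are used for *ranking*
  models under identical conditions, where a shared bias largely cancels.
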