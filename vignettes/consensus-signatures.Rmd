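---
title: "Consensus miRNA signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus miRNA signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirsign)
```

This vignette documents the model behind `mirsign`, the parameters that
matter, the numerical conventions, and the design decisions taken where the
design was genuinely open. It states no empirical result beyond what the
package's test suite computes.

## The consensus selection model

The object of interest is a compact signature of miRNA features that
supports classification of tumor samples across classifiers of different
typologies. The selection procedure treats every *(classifier family, run)*
pair as one **classifier instance**:

1. draw a fresh stratified k-fold partition (default 10 folds) from the
   instance's sub-seed;
2. for each fold, standardize using statistics of that fold's training part
   only, fit the classifier, and extract a per-feature importance vector —
   split counts for tree ensembles, summed absolute coefficients for linear
   models;
3. average the fold-level importance vectors into one instance-level vector
   and rank its top `top_k_tally` features (default 100).

Across all instances, each feature's tally N~t~ (the number of instances
ranking it in their top-k) is converted to the consensus score
s~f~ = N~t~/N~c~, and the `signature_size` highest-scoring features form the
signature. Because only *relative ranking* enters the tally, the
heterogeneous numeric scales of split counts and coefficient magnitudes
never need to be commensurable — this is the central assumption of the
method, and also its main simplification: a feature ranked 101st by every
instance scores 0, identical to a feature ranked last.

### Instance granularity

With 8 families and 10 runs the ensemble reports N~c~ = 80. A run, however,
contains 10 fold-level fits. We resolve this by averaging the 10 per-fold
importance vectors into one list per run, which keeps N~c~ = 80 while using
every fold's information. The alternative — one ranked list per fold,
N~c~ = 800 — would weight families with noisier fold-to-fold rankings
differently; averaging first is the more conservative reading.

### Tie handling

All orderings are made deterministic: `rank_top_k` breaks importance ties
by ascending feature name; `select_signature` orders by descending s~f~,
then descending N~t~ (redundant when all instances share N~c~), then
ascending name. Determinism across platforms is worth the small bias toward
lexicographically early names among exactly tied features.

### Seed ladder

A single master seed spawns per-instance sub-seeds by fixed enumeration
order (`child_seed`, a Lehmer-style mixing of seed and index, bounded below
2^31). Instances are therefore independent of execution order and could be
run concurrently with merge-order-independent results.

## The classifier roster

| family | implementation | importance |
|---|---|---|
| gradient_boosting | xgboost, 300 rounds, depth 3, η = 0.1 | split counts |
| random_forest | ranger, 300 trees, mtry = √p | split counts |
| bagging_trees | ranger, 300 trees, mtry = p | split counts |
| logistic_regression | glmnet ridge-path, λ = 10⁻³ | Σ |coef| |
| ridge | closed-form one-vs-rest ridge regression, λ = 1 | Σ |coef| |
| svc_linear | e1071 linear SVM, one-vs-rest, C = 1 | Σ |coef| |
| passive_aggressive | PA-I online updates, C = 1, 5 epochs | Σ |coef| |
| sgd_linear | SGD on hinge loss, L2 α = 10⁻⁴, 5 epochs | Σ |coef| |

Tree ensembles use 300 predictors and the support-vector classifier a
linear kernel; remaining settings are library defaults. Notes:

* **Split counting is raw.** Importance for tree models is the count of
  internal splits using the feature — not impurity-weighted, not
  depth-weighted. Weighted variants would implicitly re-scale typologies
  that the tally deliberately treats as rank-only.
* **Multiclass linear reduction.** One-vs-rest coefficient rows are
  aggregated by the sum of absolute values: symmetric in the classes,
  monotone in every row, and invariant to global rescaling.
* **Linear SVC is fitted one-vs-rest** (not the one-vs-one decomposition
  some libraries default to) so that a well-defined classes × features
  weight matrix exists. The decision-value sign of each binary fit is
  oriented empirically on the training data, because the underlying library
  fixes it by class-appearance order.
* **Passive-aggressive and SGD are implemented in-package** as standard
  online one-vs-rest updates (PA-I closed-form step; hinge-loss SGD with an
  inverse-time learning-rate decay). They are simple algorithms and their
  coefficient matrices plug into the same importance extraction as the
  other linear models.
* **Bagged trees are a random forest with mtry = p**: bootstrap aggregation
  of unrestricted trees is exactly bagging, fitted by the same engine as
  the forest.

## Standardization and folds

Standardization removes the per-feature mean and scales to unit variance,
with the **population SD convention** (divide by n). The convention is
recorded in the model object and the run report (`sd_convention`), since
either choice is defensible and they differ at small n. The model is always
learned on the training partition and applied unchanged to held-out or
external data. Constant training features receive a substitute SD of 1 and
a flag, so the transform is defined and downstream consumers can ignore
them.

Stratified folds deal each class's shuffled samples round-robin, rotating
the starting fold between classes; per-fold class counts are within one
sample of proportional for every class. Classes smaller than the fold count
are assigned with a warning (some folds then lack the class).

## Baseline selectors

* **UFS** scores features by the one-way ANOVA F statistic; constant
  features get F = 0 and rank last.
* **RFE** removes exactly one feature per iteration (the smallest summed
  |coefficient| of a linear SVC by default), giving the predictable cost of
  N − k fits.
* **LASSO / elastic net** (mixing 0.5) choose the penalty by internal
  3-fold CV and rank by aggregated |coefficient|; zero-coefficient features
  rank below all nonzero ones in name order, and a selection forced to dip
  into them is flagged as padded.
* **EFS-CLA** averages |weights| of 40 linear SVMs per iteration, each on a
  random 50% subsample (the subsample fraction is not fixed by the
  method's published summary; 50% without replacement is this package's
  documented choice), and drops the bottom 20% (floored, ≥ 1) of surviving
  features. When a reduction would undershoot k, the survivors are trimmed
  to exactly k by weight, so the result always has exactly k features.
* **Random selection** provides the chance floor for every comparison.

## Evaluation battery

Accuracy is the plain fraction of correct predictions (micro accuracy);
per-class accuracy is recall, and the class-size-weighted mean of per-class
accuracies reproduces global accuracy exactly — both are reported
separately rather than folded into a balanced accuracy. Paired comparisons
use the per-fold accuracy samples; pairing is at fold granularity (the
alternative, per-run pairing, discards within-run variance). When every
paired difference is identical the t statistic is undefined; this is
reported as a `degenerate_variance` flag (p = 1 if the common difference is
zero) because it legitimately occurs on deterministic toy problems.
Cross-dataset evaluation intersects feature sets automatically and reports
the common-feature count.

Run reports deliberately contain no wall-clock fields: byte-identical
outputs under identical seeds are a contract of every entry point, and
timings would break it for no analytical gain.

## Cross-platform mapping

External array data arrives as per-feature z-scores over mature-sequence
features. Mapping into the reference (sequencing) space proceeds in three
steps:

1. **mature → stem-loop reconciliation**: each stem-loop feature is tied to
   its most common mature sequence, so the relationship is a column copy;
   several stem-loop loci producing the same mature sequence receive
   identical copies. The general linear combination over all mature
   products of a precursor is deliberately reduced to this dominant term —
   the residual terms are absorbed into the platform scale fitted next.
2. **z-score unfolding**: X~i~ = (Z~i~·σ~i~ + μ~i~)·a~i~ with μ, σ the
   reference column statistics and a~i~ a positive per-feature platform
   scale.
3. **scale calibration**: a is fitted by minimizing the root-mean-squared
   difference between integer class codes predicted by a reference-trained
   classifier on the mapped data and the actual codes. Class codes are
   assigned by sorted class-name order on the reference dataset — a fixed
   integer coding is required because the objective subtracts classes, and
   sorted order is the reproducible choice.

The objective is piecewise constant in a (it changes only when a prediction
flips), so gradient methods are unsuitable. The optimizer is a (1+1)
evolution strategy on log(a): log-normal full-vector mutations, step size
adapted by the 1/5th success rule (bounded to [10⁻³, 2]), default budget
5000 evaluations. The walker accepts equal-objective moves — necessary to
traverse plateaus — but only strictly improving points are recorded as the
result, so the returned scale can never drift along a plateau away from the
initial guess, and the final objective never exceeds the initial one. If
the budget is exhausted without any strict improvement the initial scale is
returned with a warning. Identifiability of a is only through the
classifier's decision boundaries: features the classifier barely uses are
weakly constrained, which is why recovery tolerances in the tests are
deliberately loose (median relative error, not per-feature error).

## The synthetic generator

`synthetic_spec()` emulates the structure of a pan-cancer miRNA-seq
compendium: expression is exp(Normal) — positive and heavy-tailed like RPM
values — with per-feature baseline abundances jittered around a common
log-space location (default location 3, scale 1, i.e. typical values of a
few tens of RPM spanning orders of magnitude). Class labels follow
user-specified, typically unbalanced proportions (largest-remainder
rounding keeps counts within one sample of exact). Each planted informative
feature is a **marker of one class**, up-shifted by `effect_size` log-SD
units in that class only, with marker classes assigned by cycling through
the class list; with `effect_size = 0` the generator is an exact null. An
optional normal-tissue fraction relabels samples `"NT"` and withholds the
marker shift from them, for tumor-vs-normal tasks. A simulated second
platform inverts the cross-platform mapping: reference expression divided
by a true per-feature scale, z-scored by the reference statistics, plus
optional Gaussian noise.

What the generator does **not** emulate: miRNA co-expression covariance
(features are independent given the class), batch effects beyond the linear
platform model, class-specific down-regulation, and library-size artifacts.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted structure, not performance on real tumor
compendia.

### Benchmark problem sizes

The default benchmark spec is 600 samples, 8 classes with proportions
0.30/0.20/0.15/0.10/0.10/0.05/0.05/0.05, 200 features of which 20 are
informative at effect 1.5. The test suite runs the full 8-family roster on
it with 2 runs per family (N~c~ = 16) and 100 predictors per tree ensemble,
and the evaluation battery with a single 10-fold repeat — problem sizes
chosen so the whole suite completes in minutes on one CPU while preserving
the unbalanced multiclass character of the motivating data. Full-scale
settings (10 runs, 300 predictors, k = 100 on ~1000 features) remain the
package defaults.

On this benchmark the reduced signature *gains* accuracy for the linear
families — removing 180 noise features helps them most — so the
full-vs-reduced check in the tests asserts the one-sided bound (the
signature concedes at most 3 accuracy points), which is the substantive
claim behind signature reduction.

## Known limitations

* Consensus scores are tied to the tally depth k; features of rank just
  beyond k in many instances are invisible to the score.
* The platform scale is only identified through the reference classifier;
  with a perfectly separable external dataset the objective reaches zero
  before the scales are individually resolved.
* The online linear classifiers (PA, SGD) are sensitive to sample order;
  they are epoch-shuffled from the instance seed, so their rankings are
  reproducible but depend on the seed more than the batch solvers do.
* `read_expression_tsv` loads the full matrix into memory; the package
  targets matrices of thousands of samples by ~10³ features, not
  single-cell scale.
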