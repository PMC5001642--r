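---
title: "Evaluating classifiers with cross-validation and cross-testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating classifiers with cross-validation and cross-testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstesting)
```

## The problem

With limited labeled data, a supervised-classification study faces a
three-way trade-off between generalization performance, the interpretability
of the choices it reports, and data efficiency.  The conventional
**cross-validation and testing** design splits the data once into a
cross-validation set (used k-fold to select parameters such as the
preprocessing and the misclassification penalty) and a held-out test set
(used once to estimate accuracy).  Every sample given to the test set is a
sample unavailable for selection and fitting, so enlarging the test set to
gain statistical power directly degrades the model being assessed.
**Nested cross-validation** removes the trade-off by letting every sample be
test data once in an outer loop, with an inner loop selecting parameters per
outer fold — but then each fold may select different parameters and there is
no single combination left to report.

**Cross-validation and cross-testing** interpolates between the two.
Parameters are selected exactly as in the conventional design, on the
cross-validation set only, so one interpretable combination is chosen.  The
novelty is the testing stage: the test set is partitioned into $k'$
stratified folds, and each fold is scored by a model trained (with the
already-fixed parameters) on the *entire cross-validation set plus the other
$k' - 1$ test folds*.  The $k'$ fold accuracies are averaged.  Every scored
sample is still outside the training data of the model that scores it, so
the estimate is unbiased in the leakage sense, yet almost all of the data
participate in each model fit.  The price is that no single fitted model
survives — only the parameters do.

`evaluate_cv_and_test()`, `evaluate_nested_cv()` and
`evaluate_cv_and_crosstest()` implement the three designs;
`cross_test()` is the novel testing stage in isolation.

```{r example}
d <- generate_simulated(per_subgroup = 50, seed = 1)  # 200 samples
evaluate_cv_and_test(d, seed = 7)
evaluate_cv_and_crosstest(d, seed = 7)
evaluate_nested_cv(d, seed = 7)
```

## The candidate-model grid

The default search space, `default_grid()`, crosses a preprocessing choice —
raw features versus PCA retaining the smallest number of components with at
least 70% cumulative variance — with three values of the soft-margin SVM
penalty, $c \in \{10^{-4}, 10^{-2}, 1\}$: six combinations.  All k-fold
parameters default to 5.  The grid's row order is part of its contract:
ties in mean cross-validation accuracy go to the earliest row, which makes
selection deterministic.

Two choices the grid's description leaves genuinely open are made here as
package defaults:

* **Kernel.**  The benchmark classes are constructed to be linearly
  inseparable (an XOR-like arrangement in the first two feature dimensions),
  yet they must be learnable, so the default classifier is an RBF-kernel SVM
  (`e1071::svm`).  The bandwidth is the feature-scaled default
  $\gamma = 1/d$ on standardized features.  Any classifier honouring the
  `fit(x, y, params)` / `predict(object, x)` contract can be plugged in;
  the test suite uses a deterministic 1-nearest-neighbour plug-in as an
  enumerable oracle.
* **Standardization.**  Penalty values spanning four orders of magnitude
  are meaningless without a fixed feature scale, so features are centred and
  scaled to unit variance using *training-partition statistics only*, and
  PCA is likewise fitted on the training partition only.  Evaluation data
  never influence the transform.

A training partition containing a single class (possible in extreme sweeps,
e.g. 50 samples with 90% held out) yields a constant predictor flagged as a
fallback rather than an error, so Monte-Carlo sweeps always complete; the
per-replicate logs count these fallbacks.

## Partitioning rules

All splits and folds are **stratified**: within each class, indices are
shuffled and dealt round-robin (`make_folds()`), and the one-off
cross-validation/test split takes `round(test_fraction * n_class)` per class
(`split_cv_test()`).  Stratification is a package decision — it prevents
silent single-class partitions at the smallest sample sizes, and a split
that would still leave a class absent from either side raises an error
instead of corrupting downstream estimates.

Randomness is organized in named substreams derived from one seed
(`mix_seed()`).  The split and the selection stage of the two split-based
schemes share substreams, so at the same seed they select the *same*
parameter combination and differ only in their testing stage; this isolates
the schemes' actual difference in any paired comparison.  With $k' = 1$,
`cross_test()` reduces *exactly* to plain holdout testing — a reduction the
test suite asserts as an identity, not approximately.

Cross-testing aggregates fold accuracies by unweighted mean by default
(fold sizes differ by at most one under stratified dealing); pooled
total-correct/total-scored aggregation is available via `aggregate =
"pooled"`.

## Permutation significance and the randomized correction

Whether an accuracy is above chance is decided by a permutation test
(`permutation_test()`): the label vector is permuted uniformly at random
$N$ times (default 1000; the sweep drivers default to 199 at desk scale),
the evaluation pipeline is re-run on each relabelled dataset, and with $b$
permuted accuracies at least the observed and $b_s$ strictly above it,

$$p_{\ge} = \frac{b + 1}{N + 1}, \qquad p_{>} = \frac{b_s}{N + 1}.$$

Each permuted replicate re-draws its data split and fold assignments from
its own substream, jointly with the relabelling, so the $N + 1$ pipeline
runs are exchangeable under the null.  Accuracy comparisons use a $10^{-12}$
absolute tolerance: accuracies are ratios of small integers, and exact ties
are meaningful and must not be split by floating-point noise.

Because the permutation distribution is discrete, the plain rule
"reject when $p_{\ge} \le \alpha$" is conservative — its realized size can
sit well below $\alpha$.  `randomized_decision()` applies the classical
randomized exact rule: reject outright when $p_{\ge} \le \alpha$, accept
outright when $p_{>} \ge \alpha$, and otherwise reject with probability

$$\frac{\alpha - p_{>}}{p_{\ge} - p_{>}},$$

which makes the test exactly size $\alpha$ under exchangeability, ties
included.  When no ties occur and $\alpha$ is attainable as $k/(N+1)$, the
randomized rule coincides with the plain rule, which remains available as
`rule = "plain"`.

Two permutation **modes** are provided because how the selection stage is
treated under permutation is genuinely open.  `full_rerun` (the default)
re-runs parameter selection inside every permuted replicate — unambiguously
valid under the null, and the only defined option for nested CV.
`fixed_selection` freezes the combination selected on the true labels and
re-runs only the testing stage, which is several-fold faster; the
random-label calibration experiments are the check of its validity, and at
the package's check scale (below) its realized false-positive rate is
statistically indistinguishable from $\alpha$.

## Synthetic benchmarks

`generate_simulated()` emulates a linearly inseparable two-class problem:
all features uniform on $[0,1]$, then class A is an equal mixture of
{no shift} and {dimensions 1 and 2 shifted by 0.8} while class B mixes
{dimension 1 shifted} and {dimension 2 shifted}.  Defaults: 2000 samples per
subgroup (8000 total), 6 features, offset 0.8.  In the first two dimensions
each class's mean is $(0.5 + 1.3)/2 = 0.9$, identical across classes, so no
linear boundary helps; the class difference lives in the joint arrangement.
Dimensions 3+ are pure noise.  Rows are shuffled before return so contiguous
subsets are still random.

`generate_random()` emulates the matching null: uniform features, labels
independent fair coin flips (defaults 10000 samples, 20 features).  Any
pipeline run on it should report chance accuracy and reject at $\alpha$.

What these generators do **not** emulate: correlated or heavy-tailed
features, class imbalance, label noise, non-stationarity, and the
dimensionalities of real electrophysiological data.  Passing checks on them
demonstrates the partitioning arithmetic, the absence of leakage and the
calibration of the test — not performance claims about any real recording
modality.  Real tabular datasets enter as CSV (`read_dataset_csv()`: header
row, a `label` column, numeric features).

## Sweep experiments

`sweep_dataset_size()` varies the total subsample size drawn from a
reference dataset at a fixed test fraction (default 50%);
`sweep_test_fraction()` fixes the size (default 100) and varies the held-out
fraction (the canonical sweep uses 10%–90%; nested CV has no test fraction
and is rejected there).  Each cell runs `n_reps` independent replicates of
`run_one()` — stratified subsample, scheme, permutation test — and reports
mean accuracy and the proportion of significant results with Monte-Carlo
standard errors.  Every replicate is a pure function of
`(master_seed, condition, scheme, rep_index)`, so whole sweeps are
bit-reproducible and any single replicate can be reproduced in isolation.

Desk-scale defaults are `n_reps = 100` and 199 permutations (the full-scale
design behind the reference curves uses 1000 of each); both are plain
arguments, and the reported standard errors keep reduced-scale comparisons
honest.

## Check scale and expected behaviour

The package's own statistical checks run at these problem sizes, chosen so
the whole suite completes comfortably on one CPU while keeping Monte-Carlo
error well below the tolerances asserted:

* Null calibration of the full cross-testing pipeline: 100 stratified
  $n = 100$ subsamples of a 10,000-sample random-label reference
  (20 features), 199 permutations each, `fixed_selection`; the significant
  count must fall in the 95% binomial band around 0.05 and mean accuracy
  within $0.50 \pm 0.04$.  (Replicates are drawn from a common reference,
  as in the sweep experiments, rather than generated independently: a
  directly generated $n = 100$ dataset carries binomial class imbalance
  that a weakly-penalized classifier can exploit as a majority vote,
  shifting mean null accuracy visibly above 0.5 even though the calibration
  of the significance test is unaffected.)
* Scheme ordering on the simulated benchmark ($n = 100$ subsamples of the
  8000-sample reference, 50% test, 200 seeds): nested $\ge$ cross-testing
  $\ge$ plain testing in mean accuracy within 0.02, all above chance by
  more than 5 pooled standard errors.
* Exact size of the randomized rule: 1000 simulated discrete nulls
  ($n = 16$, 1-NN plug-in, 39 permutations); rejection rate inside the 95%
  binomial band around 0.05, and within 0.03 of the plain rule.
* Leakage audit: an instrumented classifier records the sample ids of every
  training set and every scored batch; across all three schemes the two id
  sets never intersect, and every cross-testing training set contains the
  whole cross-validation set.

## Known limitations

* Two classes only; multi-class designs would need a different chance level
  and stratification bookkeeping.
* The randomized decision makes a per-run coin flip at the boundary: two
  analysts with different seeds can legitimately disagree on a single run's
  significance.  That is the price of exact size on a discrete null; report
  `p_geq`/`p_gt` alongside the decision.
* `fixed_selection` is a computational shortcut whose validity is
  empirical (calibration-checked), not structural like `full_rerun`.
* Accuracy is the only performance metric; AUC or balanced error would need
  a different tie structure in the permutation test.
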