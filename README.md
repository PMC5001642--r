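# crosstesting

Evaluation schemes for two-class supervised classification when data are
scarce and the *parameters* of the analysis — the preprocessing choice, the
misclassification penalty — need to be reported and interpreted, not just
the accuracy.

The conventional design ("cross-validation and testing") splits the data
once: a cross-validation set selects the best parameter combination by
k-fold CV, a held-out test set estimates accuracy.  Every sample reserved
for testing is lost to model fitting, so statistical power and model quality
trade off directly.  Nested cross-validation removes the trade-off but
leaves no single parameter combination to report.  This package implements
the interpolation between the two, **cross-validation and cross-testing**:
parameters are selected once on the cross-validation set, and the test set
is then scored by a modified cross-validation — partition the test set into
k′ stratified folds and score each fold with a model trained, at the fixed
parameters, on the entire cross-validation set plus the other k′ − 1 test
folds:

    accuracy = (1/k′) Σ_f  acc( fit(θ*, CV ∪ (T \ T_f)),  T_f )

No scored sample is ever in its scoring model's training data, so the
estimate stays leakage-free while nearly all data contribute to every fit.

Significance against chance is a permutation test: labels are permuted N
times, the pipeline re-run each time, p_≥ = (b + 1)/(N + 1).  Because
accuracies are ratios of small integers the permutation null is discrete,
and the package applies the randomized exact decision rule — reject with
probability (α − p_>)/(p_≥ − p_>) when the attainable p-values straddle α —
so the test has size exactly α.

Also included: stratified splitting/folding, an SVM+PCA parameter grid with
a pluggable classifier contract, synthetic benchmark generators (a linearly
inseparable XOR-like two-class design and a random-label null design),
Monte-Carlo sweep drivers over data-set size and test-set fraction, and a
small CLI (`inst/cli/crosstesting.R`).

## Worked example

```r
library(crosstesting)

d <- generate_simulated(per_subgroup = 50, seed = 1)  # 200 samples, 6 features
d
#> <ct_dataset> 200 samples x 6 features
#>   class counts: 0=100, 1=100

evaluate_cv_and_test(d, seed = 7)
#> <ct_result> scheme: cv_and_test | accuracy: 0.62
#>   selected: pca@0.7,c=1

evaluate_cv_and_crosstest(d, seed = 7)
#> <ct_result> scheme: cv_and_crosstest | accuracy: 0.66
#>   selected: pca@0.7,c=1

evaluate_nested_cv(d, seed = 7)
#> <ct_result> scheme: nested_cv | accuracy: 0.645
#>   no single parameter combination (per-fold selection)
```

At the same seed both split-based schemes select the same combination (here
PCA at 70% variance with penalty c = 1, printed as `pca@0.7,c=1`), so the
accuracy difference — 0.66 versus 0.62 — is attributable to the testing
stage alone: cross-testing fits each scoring model on ~180 of the 200
samples instead of 100.  Nested CV, which may pick different parameters per
outer fold, lands in between here.  Attach a permutation test with
`permutation_significance(d, "cv_and_crosstest", seed = 7)`; sweep sample
sizes or test fractions with `sweep_dataset_size()` /
`sweep_test_fraction()`.

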