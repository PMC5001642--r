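#' Randomized decision rule for a discrete permutation null
#'
#' Permutation accuracies are ratios of small integers, so the attainable
#' p-values form a coarse lattice and the plain rule "reject when p <= alpha"
#' is conservative: its size can fall well below alpha.  The randomized exact
#' rule removes that bias.  With `p_geq` the inclusive tail probability
#' (permuted statistic at least the observed, observed counted once) and
#' `p_gt` the strict tail probability, the rule is:
#'
#' * `p_geq <= alpha`: reject (deterministically);
#' * `p_gt >= alpha`: accept (deterministically);
#' * otherwise the attainable p-values straddle alpha — reject with
#'   probability `(alpha - p_gt) / (p_geq - p_gt)`.
#'
#' Under exchangeability of the observed and permuted statistics this test has
#' size exactly alpha, ties included.
#'
#' @param p_geq inclusive-tail p-value.
#' @param p_gt strict-tail p-value, `0 <= p_gt <= p_geq <= 1`.
#' @param alpha significance level in (0, 1).
#' @param seed integer seed for the boundary coin flip.
#' @return list with `significant` (logical) and `randomized` (logical: did
#'   the boundary coin decide).
#' @examples
#' randomized_decision(0.011, 0.005, 0.05, seed = 1) # deterministic reject
#' @export
randomized_decision <- function(p_geq, p_gt, alpha, seed = 1) {
  if (!(p_gt >= 0 && p_gt <= p_geq && p_geq <= 1)) {
    stop("need 0 <= p_gt <= p_geq <= 1 (got p_gt = ", p_gt,
         ", p_geq = ", p_geq, ")")
  }
  stopifnot(alpha > 0, alpha < 1)
  if (p_geq <= alpha) {
    list(significant = TRUE, randomized = FALSE)
  } else if (p_gt >= alpha) {
    list(significant = FALSE, randomized = FALSE)
  } else {
    prob <- (alpha - p_gt) / (p_geq - p_gt)
    u <- local_seed(seed, runif(1))
    list(significant = u < prob, randomized = TRUE)
  }
}

#' Permutation test of classification accuracy against chance
#'
#' The generic engine: `evaluator(dataset, seed)` is any function returning an
#' accuracy — typically one of the evaluation schemes, or a frozen-parameter
#' testing stage.  The observed accuracy is computed on the true labels; for
#' each of `n_permutations` replicates the label vector is permuted uniformly
#' at random (features untouched) and the evaluator re-run with a fresh seed
#' substream, so the data split and fold assignments are re-drawn jointly with
#' the relabelling and the permuted runs are exchangeable with the observed
#' one.  With `b` permuted accuracies at least the observed and `b_strict`
#' strictly above it, `p_geq = (b + 1) / (N + 1)` and
#' `p_gt = b_strict / (N + 1)`; significance is decided by the
#' `"randomized"` rule ([randomized_decision()]) or the plain rule
#' `p_geq <= alpha`.  Accuracy comparisons use a 1e-12 tolerance so that exact
#' rational ties are never split by floating-point noise.
#'
#' @param evaluator function `(dataset, seed) -> accuracy in [0, 1]`.
#' @param dataset a [ct_dataset()].
#' @param n_permutations number of label permutations N (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed governing permutations, evaluator substreams and
#'   the boundary coin.
#' @param rule `"randomized"` (default) or `"plain"`.
#' @param observed optionally, the already-computed observed accuracy; when
#'   `NULL` it is computed as `evaluator(dataset, mix_seed(seed, "perm", 0))`.
#' @return list of class `ct_permutation`: `observed_accuracy`, `p_geq`,
#'   `p_gt`, `significant`, `randomized`, `perm_accuracies`, `n_permutations`,
#'   `alpha`, `rule`.
#' @export
permutation_test <- function(evaluator, dataset, n_permutations = 1000,
                             alpha = 0.05, seed = 1,
                             rule = c("randomized", "plain"),
                             observed = NULL) {
  rule <- match.arg(rule)
  if (n_permutations < 1) stop("`n_permutations` must be at least 1")
  stopifnot(is.function(evaluator), inherits(dataset, "ct_dataset"))
  n <- n_samples(dataset)
  if (is.null(observed)) {
    observed <- evaluator(dataset, mix_seed(seed, "perm", 0))
  }
  perm_acc <- vapply(seq_len(n_permutations), function(i) {
    ord <- local_seed(mix_seed(seed, "relabel", i), sample.int(n))
    evaluator(dataset_relabel(dataset, dataset$labels[ord]),
              mix_seed(seed, "perm", i))
  }, numeric(1))
  tol <- 1e-12
  b <- sum(perm_acc >= observed - tol)
  b_strict <- sum(perm_acc > observed + tol)
  p_geq <- (b + 1) / (n_permutations + 1)
  p_gt <- b_strict / (n_permutations + 1)
  dec <- if (rule == "randomized") {
    randomized_decision(p_geq, p_gt, alpha, mix_seed(seed, "decide"))
  } else {
    list(significant = p_geq <= alpha, randomized = FALSE)
  }
  structure(
    list(observed_accuracy = observed, p_geq = p_geq, p_gt = p_gt,
         significant = dec$significant, randomized = dec$randomized,
         perm_accuracies = perm_acc, n_permutations = as.integer(n_permutations),
         alpha = alpha, rule = rule),
    class = "ct_permutation"
  )
}

#' @export
print.ct_permutation <- function(x, ...) {
  cat("<ct_permutation> observed accuracy:",
      format(round(x$observed_accuracy, 4)),
      "| N =", x$n_permutations, "\n")
  cat("  p_geq:", format(round(x$p_geq, 4)),
      "| p_gt:", format(round(x$p_gt, 4)),
      "| significant:", x$significant,
      if (isTRUE(x$randomized)) "(randomized boundary decision)", "\n")
  invisible(x)
}

#' Run a scheme and attach permutation significance
#'
#' Convenience wrapper: runs the named scheme on the true labels, then applies
#' [permutation_test()] to it.  Two permutation modes are provided because the
#' selection stage can be handled either way:
#'
#' * `"full_rerun"` (default): every permuted replicate re-runs the whole
#'   scheme, parameter selection included — unambiguously valid under the
#'   null, and the only option for nested CV;
#' * `"fixed_selection"`: the combo selected on the true labels is frozen and
#'   only the testing stage (holdout or cross-testing) is re-run per
#'   permutation — several-fold faster; the null calibration experiments are
#'   the check of its validity.
#'
#' @inheritParams run_scheme
#' @param n_permutations,alpha,rule passed to [permutation_test()].
#' @param mode `"full_rerun"` or `"fixed_selection"` (the latter is not
#'   defined for nested CV, which has no single selected combo).
#' @return the scheme's `ct_result` with `p_geq`, `p_gt`, `significant`,
#'   `randomized` filled in, plus a `permutation` field holding the full
#'   `ct_permutation`.
#' @export
permutation_significance <- function(dataset,
                                     scheme = c("cv_and_test",
                                                "cv_and_crosstest",
                                                "nested_cv"),
                                     grid = default_grid(),
                                     test_fraction = 0.5, k_select = 5,
                                     k_test = 5, k_outer = 5, k_inner = 5,
                                     n_permutations = 1000, alpha = 0.05,
                                     mode = c("full_rerun", "fixed_selection"),
                                     rule = c("randomized", "plain"),
                                     seed = 1, classifier = svm_classifier()) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  observed <- run_scheme(dataset, scheme, grid, test_fraction, k_select,
                         k_test, k_outer, k_inner,
                         seed = mix_seed(seed, "perm", 0),
                         classifier = classifier)
  if (mode == "fixed_selection") {
    if (scheme == "nested_cv") {
      stop("mode = \"fixed_selection\" is undefined for nested_cv: ",
           "each outer fold selects its own parameters; use \"full_rerun\"")
    }
    frozen <- observed$selection$best
    evaluator <- function(d, s) {
      parts <- split_cv_test(d, test_fraction, mix_seed(s, "split"))
      if (scheme == "cv_and_test") {
        model_accuracy(fit_model(parts$cv, frozen, classifier), parts$test)
      } else {
        as.numeric(cross_test(parts$cv, parts$test, frozen, k_test,
                              mix_seed(s, "crosstest"), classifier))
      }
    }
  } else {
    evaluator <- function(d, s) {
      run_scheme(d, scheme, grid, test_fraction, k_select, k_test, k_outer,
                 k_inner, seed = s, classifier = classifier)$accuracy
    }
  }
  pt <- permutation_test(evaluator, dataset, n_permutations, alpha, seed,
                         rule, observed = observed$accuracy)
  observed$p_geq <- pt$p_geq
  observed$p_gt <- pt$p_gt
  observed$significant <- pt$significant
  observed$randomized <- pt$randomized
  observed$permutation <- pt
  observed
}
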