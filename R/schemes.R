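#' Stratified k-fold assignment
#'
#' Within each class the sample indices are shuffled and dealt round-robin
#' into `k` folds, so fold sizes within a class differ by at most one and
#' class proportions are preserved as closely as integers allow.
#'
#' @param labels integer 0/1 label vector.
#' @param k number of folds, `1 <= k <= length(labels)`.
#' @param seed integer seed.
#' @return list with `fold_of` (fold id per sample, in 1..k) and `k`.
#' @export
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 1) stop("`k` must be at least 1")
  if (k > n) stop("`k` = ", k, " exceeds the number of samples (", n, ")")
  fold_of <- integer(n)
  local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  list(fold_of = fold_of, k = as.integer(k))
}

#' Split a dataset once into a cross-validation set and a test set
#'
#' Stratified: within each class, `round(test_fraction * n_class)` samples go
#' to the test set.  Errors if any class would end up absent from either side
#' — that signals the dataset is too small for the requested fraction, and a
#' silent single-class partition would corrupt everything downstream.
#'
#' @param dataset a [ct_dataset()].
#' @param test_fraction fraction of each class held out for testing, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `cv` and `test`, both [ct_dataset()]s, disjoint,
#'   union the input.
#' @export
split_cv_test <- function(dataset, test_fraction, seed) {
  stopifnot(inherits(dataset, "ct_dataset"),
            test_fraction > 0, test_fraction < 1)
  labels <- dataset$labels
  test_idx <- integer(0)
  local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_test <- round(test_fraction * length(idx))
      if (n_test < 1 || n_test >= length(idx)) {
        stop("test_fraction = ", test_fraction, " leaves class ",
             dataset$label_levels[cls + 1L], " (", length(idx),
             " samples) absent from the cv or test set; use more data")
      }
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(cv = dataset_slice(dataset, setdiff(seq_along(labels), test_idx)),
       test = dataset_slice(dataset, test_idx))
}

#' Select parameters by k-fold cross-validation
#'
#' One stratified fold assignment is drawn and reused for every grid row; for
#' each row the mean held-out-fold accuracy is recorded, and the row with the
#' highest mean wins, ties broken by earliest grid order.  Single-class
#' training folds fall back to a constant predictor (counted, never fatal).
#'
#' @param cv_set a [ct_dataset()] with both classes and at least `k_select`
#'   samples.
#' @param grid a [default_grid()]-style data.frame.
#' @param k_select number of folds (default 5).
#' @param seed integer seed.
#' @param classifier classifier object, see [svm_classifier()].
#' @return list of class `ct_selection`: `best` (winning combo as a list),
#'   `best_index`, `table` (the grid plus `mean_cv_accuracy`), `n_fallback`.
#' @export
select_params_cv <- function(cv_set, grid, k_select = 5, seed = 1,
                             classifier = svm_classifier()) {
  stopifnot(inherits(cv_set, "ct_dataset"), nrow(grid) >= 1)
  if (n_samples(cv_set) < k_select) {
    stop("cv set has ", n_samples(cv_set), " samples, fewer than k_select = ",
         k_select)
  }
  folds <- make_folds(cv_set$labels, k_select, seed)
  n_fallback <- 0L
  mean_acc <- numeric(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    combo <- grid_combo(grid, j)
    fold_acc <- numeric(folds$k)
    for (f in seq_len(folds$k)) {
      hold <- folds$fold_of == f
      if (!any(hold)) { fold_acc[f] <- NA_real_; next }
      model <- fit_model(dataset_slice(cv_set, which(!hold)), combo, classifier)
      if (model$fallback) n_fallback <- n_fallback + 1L
      fold_acc[f] <- model_accuracy(model, dataset_slice(cv_set, which(hold)))
    }
    mean_acc[j] <- mean(fold_acc, na.rm = TRUE)
  }
  best_index <- which.max(mean_acc) # first maximum = earliest grid row
  tab <- as.data.frame(grid)
  tab$mean_cv_accuracy <- mean_acc
  structure(
    list(best = grid_combo(grid, best_index), best_index = best_index,
         table = tab, n_fallback = n_fallback),
    class = "ct_selection"
  )
}

#' @export
print.ct_selection <- function(x, ...) {
  cat("<ct_selection> best:", format_combo(x$best), "\n")
  print(x$table, ...)
  invisible(x)
}

#' Cross-testing: score a held-out test set with augmented training sets
#'
#' The test set is partitioned into `k_test` stratified folds.  Each fold is
#' scored by a model trained on the entire cross-validation set plus the other
#' `k_test - 1` test folds, so every scored sample is outside its model's
#' training data while the model benefits from nearly all of the data.  With
#' `k_test = 1` the training set is the cross-validation set alone and the
#' procedure reduces exactly to plain holdout testing.
#'
#' @param cv_set,test_set disjoint [ct_dataset()]s.
#' @param params the (already selected) parameter combo, a list.
#' @param k_test number of test folds (default 5), at most `n_samples(test_set)`.
#' @param seed integer seed for the test-fold assignment.
#' @param classifier classifier object.
#' @param aggregate `"mean"` (unweighted mean of fold accuracies, the default)
#'   or `"pooled"` (total correct over total scored).
#' @return accuracy in \[0, 1\], with attributes `fold_accuracies` and
#'   `n_fallback`.
#' @export
cross_test <- function(cv_set, test_set, params, k_test = 5, seed = 1,
                       classifier = svm_classifier(),
                       aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(cv_set, "ct_dataset"), inherits(test_set, "ct_dataset"))
  if (k_test > n_samples(test_set)) {
    stop("k_test = ", k_test, " exceeds the test-set size (",
         n_samples(test_set), ")")
  }
  folds <- make_folds(test_set$labels, k_test, seed)
  fold_acc <- numeric(folds$k)
  fold_n <- integer(folds$k)
  n_fallback <- 0L
  for (f in seq_len(folds$k)) {
    hold <- folds$fold_of == f
    train <- if (any(!hold)) {
      ct_dataset(rbind(cv_set$features, test_set$features[!hold, , drop = FALSE]),
                 c(cv_set$label_levels[cv_set$labels + 1L],
                   test_set$label_levels[test_set$labels[!hold] + 1L]),
                 label_levels = cv_set$label_levels)
    } else {
      cv_set
    }
    model <- fit_model(train, params, classifier)
    if (model$fallback) n_fallback <- n_fallback + 1L
    held <- dataset_slice(test_set, which(hold))
    fold_acc[f] <- model_accuracy(model, held)
    fold_n[f] <- n_samples(held)
  }
  acc <- if (aggregate == "mean") mean(fold_acc) else {
    sum(fold_acc * fold_n) / sum(fold_n)
  }
  structure(acc, fold_accuracies = fold_acc, n_fallback = n_fallback)
}

new_result <- function(scheme, accuracy, selection = NULL, fallback_count = 0L,
                       fold_accuracies = NULL) {
  structure(
    list(scheme = scheme, accuracy = as.numeric(accuracy),
         selection = selection, fold_accuracies = fold_accuracies,
         fallback_count = as.integer(fallback_count),
         p_geq = NA_real_, p_gt = NA_real_,
         significant = NA, randomized = NA),
    class = "ct_result"
  )
}

#' @export
print.ct_result <- function(x, ...) {
  cat("<ct_result> scheme:", x$scheme,
      "| accuracy:", format(round(x$accuracy, 4)), "\n")
  if (!is.null(x$selection)) {
    cat("  selected:", format_combo(x$selection$best), "\n")
  } else {
    cat("  no single parameter combination (per-fold selection)\n")
  }
  if (!is.na(x$p_geq)) {
    cat("  p_geq:", format(round(x$p_geq, 4)),
        "| p_gt:", format(round(x$p_gt, 4)),
        "| significant:", x$significant,
        if (isTRUE(x$randomized)) "(randomized boundary decision)", "\n")
  }
  invisible(x)
}

#' Evaluation scheme: cross-validation and testing
#'
#' The data are split once into a cross-validation set and a test set.
#' Parameters are selected by k-fold cross-validation on the cv set, one model
#' is fitted with the winning combo on the whole cv set, and its accuracy on
#' the untouched test set is reported.  Both the selected parameters and the
#' final fitted model remain interpretable; the price is that the test samples
#' never help fit the model.
#'
#' The split and the selection stage draw their randomness from substreams
#' shared with [evaluate_cv_and_crosstest()], so at the same seed both schemes
#' select the same parameters and differ only in the testing stage.
#'
#' @param dataset a [ct_dataset()].
#' @param grid parameter grid (default [default_grid()]).
#' @param test_fraction fraction held out for testing (default 0.5).
#' @param k_select selection folds (default 5).
#' @param seed integer seed.
#' @param classifier classifier object.
#' @return a `ct_result`.
#' @export
evaluate_cv_and_test <- function(dataset, grid = default_grid(),
                                 test_fraction = 0.5, k_select = 5, seed = 1,
                                 classifier = svm_classifier()) {
  parts <- split_cv_test(dataset, test_fraction, mix_seed(seed, "split"))
  sel <- select_params_cv(parts$cv, grid, k_select, mix_seed(seed, "select"),
                          classifier)
  model <- fit_model(parts$cv, sel$best, classifier)
  new_result("cv_and_test", model_accuracy(model, parts$test), sel,
             fallback_count = sel$n_fallback + model$fallback)
}

#' Evaluation scheme: cross-validation and cross-testing
#'
#' Identical to [evaluate_cv_and_test()] through the split and parameter
#' selection (same RNG substreams, so the same seed selects the same combo),
#' but the test set is then scored by [cross_test()]: `k_test` models, each
#' trained on the cv set plus all but one test fold and scored on the held-out
#' fold, their accuracies averaged.  Parameters stay interpretable; there is
#' no single final model.
#'
#' @inheritParams evaluate_cv_and_test
#' @param k_test cross-testing folds (default 5).
#' @param aggregate passed to [cross_test()].
#' @return a `ct_result`.
#' @export
evaluate_cv_and_crosstest <- function(dataset, grid = default_grid(),
                                      test_fraction = 0.5, k_select = 5,
                                      k_test = 5, seed = 1,
                                      classifier = svm_classifier(),
                                      aggregate = c("mean", "pooled")) {
  parts <- split_cv_test(dataset, test_fraction, mix_seed(seed, "split"))
  sel <- select_params_cv(parts$cv, grid, k_select, mix_seed(seed, "select"),
                          classifier)
  acc <- cross_test(parts$cv, parts$test, sel$best, k_test,
                    mix_seed(seed, "crosstest"), classifier,
                    aggregate = match.arg(aggregate))
  new_result("cv_and_crosstest", as.numeric(acc), sel,
             fallback_count = sel$n_fallback + attr(acc, "n_fallback"),
             fold_accuracies = attr(acc, "fold_accuracies"))
}

#' Evaluation scheme: nested cross-validation
#'
#' An outer stratified k-fold loop estimates accuracy; inside each outer
#' training portion an inner cross-validation selects parameters for that fold
#' only.  Every sample is scored exactly once, by a model that never saw it,
#' so the data are used maximally — but each outer fold may pick different
#' parameters, so the result carries no single interpretable combo (its
#' `selection` is `NULL`).
#'
#' @inheritParams evaluate_cv_and_test
#' @param k_outer outer folds (default 5).
#' @param k_inner inner selection folds (default 5).
#' @return a `ct_result` with `selection = NULL`.
#' @export
evaluate_nested_cv <- function(dataset, grid = default_grid(), k_outer = 5,
                               k_inner = 5, seed = 1,
                               classifier = svm_classifier()) {
  folds <- make_folds(dataset$labels, k_outer, mix_seed(seed, "outer"))
  fold_acc <- numeric(folds$k)
  n_fallback <- 0L
  for (f in seq_len(folds$k)) {
    hold <- folds$fold_of == f
    outer_train <- dataset_slice(dataset, which(!hold))
    sel <- select_params_cv(outer_train, grid, k_inner,
                            mix_seed(seed, "inner", f), classifier)
    model <- fit_model(outer_train, sel$best, classifier)
    n_fallback <- n_fallback + sel$n_fallback + model$fallback
    fold_acc[f] <- model_accuracy(model, dataset_slice(dataset, which(hold)))
  }
  new_result("nested_cv", mean(fold_acc), selection = NULL,
             fallback_count = n_fallback, fold_accuracies = fold_acc)
}

#' Run one evaluation scheme by name
#'
#' Thin dispatcher used by the permutation test and the sweep drivers.
#'
#' @param dataset a [ct_dataset()].
#' @param scheme one of `"cv_and_test"`, `"cv_and_crosstest"`, `"nested_cv"`.
#' @param grid,test_fraction,k_select,k_test,k_outer,k_inner,seed,classifier
#'   passed to the scheme function.
#' @return a `ct_result`.
#' @export
run_scheme <- function(dataset,
                       scheme = c("cv_and_test", "cv_and_crosstest", "nested_cv"),
                       grid = default_grid(), test_fraction = 0.5,
                       k_select = 5, k_test = 5, k_outer = 5, k_inner = 5,
                       seed = 1, classifier = svm_classifier()) {
  scheme <- match.arg(scheme)
  switch(scheme,
    cv_and_test = evaluate_cv_and_test(dataset, grid, test_fraction, k_select,
                                       seed, classifier),
    cv_and_crosstest = evaluate_cv_and_crosstest(dataset, grid, test_fraction,
                                                 k_select, k_test, seed,
                                                 classifier),
    nested_cv = evaluate_nested_cv(dataset, grid, k_outer, k_inner, seed,
                                   classifier)
  )
}
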