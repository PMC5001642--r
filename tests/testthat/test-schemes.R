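test_that("stratified folds cover all samples with balanced dealing", {
  labs <- rep(c(0L, 1L), 5)
  f <- make_folds(labs, 5, seed = 1)
  expect_equal(sort(unique(f$fold_of)), 1:5)
  expect_true(all(table(f$fold_of) == 2))
  for (k in 1:5) expect_equal(sort(labs[f$fold_of == k]), c(0L, 1L))

  one <- make_folds(labs, 1, seed = 1)
  expect_true(all(one$fold_of == 1L))

  # 4 + 3 samples into 3 folds: total sizes {3,2,2}, per-class spread <= 1
  labs73 <- c(rep(0L, 4), rep(1L, 3))
  f73 <- make_folds(labs73, 3, seed = 2)
  expect_equal(sort(as.vector(table(f73$fold_of)), decreasing = TRUE),
               c(3L, 2L, 2L))
  for (cls in 0:1) {
    sizes <- table(factor(f73$fold_of[labs73 == cls], levels = 1:3))
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(make_folds(labs, 11, seed = 1), "exceeds")
})

test_that("split_cv_test is stratified, exhaustive and seed-deterministic", {
  d <- generate_simulated(per_subgroup = 25, seed = 1) # 100 samples 50/50
  parts <- split_cv_test(d, 0.5, seed = 3)
  expect_equal(n_samples(parts$cv), 50L)
  expect_equal(n_samples(parts$test), 50L)
  expect_equal(as.vector(table(parts$test$labels)), c(25L, 25L))
  ids <- c(rownames(parts$cv$features), rownames(parts$test$features))
  expect_setequal(ids, rownames(d$features))

  parts9 <- split_cv_test(d, 0.9, seed = 3)
  expect_equal(n_samples(parts9$cv), 10L)
  expect_equal(as.vector(table(parts9$cv$labels)), c(5L, 5L))

  again <- split_cv_test(d, 0.5, seed = 3)
  expect_identical(parts, again)
  other <- split_cv_test(d, 0.5, seed = 4)
  expect_false(setequal(rownames(parts$test$features),
                        rownames(other$test$features)))

  tiny <- ct_dataset(matrix(runif(8), 4, 2), c(0L, 0L, 1L, 1L))
  expect_error(split_cv_test(tiny, 0.9, seed = 1), "absent")
})

test_that("select_params_cv matches a brute-force oracle and breaks ties by order", {
  d <- generate_random(10, 2, seed = 6)
  g <- grid_one_combo()
  sel <- select_params_cv(d, g, k_select = 5, seed = 11,
                          classifier = one_nn_classifier())
  # oracle: same fold assignment, fold accuracies by brute-force 1-NN
  folds <- make_folds(d$labels, 5, seed = 11)
  fold_acc <- vapply(1:5, function(f) {
    tr <- folds$fold_of != f
    mtr <- d$features[tr, , drop = FALSE]
    # the package standardizes with training statistics; mirror that
    mu <- colMeans(mtr); sdev <- apply(mtr, 2, sd); sdev[sdev < 1e-12] <- 1
    pred <- nn_oracle_predict(scale(mtr, mu, sdev), d$labels[tr],
                              scale(d$features[!tr, , drop = FALSE], mu, sdev))
    mean(pred == d$labels[!tr])
  }, numeric(1))
  expect_equal(sel$table$mean_cv_accuracy, mean(fold_acc))
  expect_equal(sel$best_index, 1L)

  # duplicate combo rows tie exactly; the earliest row must win
  g2 <- rbind(as.data.frame(g), as.data.frame(g))
  class(g2) <- c("ct_grid", "data.frame")
  sel2 <- select_params_cv(d, g2, k_select = 5, seed = 11,
                           classifier = one_nn_classifier())
  expect_equal(sel2$best_index, 1L)
  expect_equal(sel2$table$mean_cv_accuracy[1], sel2$table$mean_cv_accuracy[2])
})

test_that("cross_test reduces exactly to holdout at k_test = 1", {
  for (s in 1:10) {
    d <- generate_random(30, 3, seed = s)
    parts <- split_cv_test(d, 0.5, seed = s)
    holdout <- model_accuracy(
      fit_model(parts$cv, combo_raw(), one_nn_classifier()), parts$test)
    ct <- cross_test(parts$cv, parts$test, combo_raw(), k_test = 1, seed = s,
                     classifier = one_nn_classifier())
    expect_identical(as.numeric(ct), holdout)
  }
  expect_error(cross_test(parts$cv, parts$test, combo_raw(), k_test = 99,
                          seed = 1), "exceeds")
})

test_that("cross_test fold accuracies match hand enumeration with 1-NN", {
  cv <- generate_random(12, 2, seed = 21)
  test <- generate_random(12, 2, seed = 22)
  ct <- cross_test(cv, test, combo_raw(), k_test = 3, seed = 5,
                   classifier = one_nn_classifier())
  folds <- make_folds(test$labels, 3, seed = 5)
  oracle_acc <- vapply(1:3, function(f) {
    keep <- folds$fold_of != f
    tx <- rbind(cv$features, test$features[keep, , drop = FALSE])
    ty <- c(cv$labels, test$labels[keep])
    mu <- colMeans(tx); sdev <- apply(tx, 2, sd); sdev[sdev < 1e-12] <- 1
    pred <- nn_oracle_predict(scale(tx, mu, sdev), ty,
                              scale(test$features[!keep, , drop = FALSE],
                                    mu, sdev))
    mean(pred == test$labels[!keep])
  }, numeric(1))
  expect_equal(attr(ct, "fold_accuracies"), oracle_acc)
  expect_equal(as.numeric(ct), mean(oracle_acc))
  # pooled aggregation equals total-correct over total-scored
  pooled <- cross_test(cv, test, combo_raw(), k_test = 3, seed = 5,
                       classifier = one_nn_classifier(), aggregate = "pooled")
  sizes <- as.vector(table(folds$fold_of))
  expect_equal(as.numeric(pooled), sum(oracle_acc * sizes) / sum(sizes))
})

test_that("the two split-based schemes share their selection at a common seed", {
  d <- generate_simulated(per_subgroup = 20, seed = 2)
  a <- evaluate_cv_and_test(d, seed = 13, classifier = one_nn_classifier())
  b <- evaluate_cv_and_crosstest(d, seed = 13, classifier = one_nn_classifier())
  expect_identical(a$selection, b$selection)
  # and k_test = 1 collapses cross-testing onto plain testing entirely
  b1 <- evaluate_cv_and_crosstest(d, k_test = 1, seed = 13,
                                  classifier = one_nn_classifier())
  expect_identical(b1$accuracy, a$accuracy)
})

test_that("nested CV with a single-combo grid equals plain outer-fold CV", {
  d <- generate_random(20, 3, seed = 31)
  res <- evaluate_nested_cv(d, grid_one_combo(), k_outer = 4, k_inner = 2,
                            seed = 17, classifier = one_nn_classifier())
  expect_null(res$selection)
  folds <- make_folds(d$labels, 4, seed = mix_seed(17, "outer"))
  oracle <- mean(vapply(1:4, function(f) {
    tr <- folds$fold_of != f
    m <- fit_model(d[which(tr)], combo_raw(), one_nn_classifier())
    model_accuracy(m, d[which(!tr)])
  }, numeric(1)))
  expect_equal(res$accuracy, oracle)
})

test_that("all three schemes score separable data perfectly", {
  d <- separable_clouds(n_per_class = 15, seed = 9)
  expect_equal(evaluate_cv_and_test(d, seed = 1)$accuracy, 1.0)
  expect_equal(evaluate_cv_and_crosstest(d, seed = 1)$accuracy, 1.0)
  expect_equal(evaluate_nested_cv(d, seed = 1)$accuracy, 1.0)
})
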