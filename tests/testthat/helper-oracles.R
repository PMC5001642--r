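# Independent oracles and instrumentation used across the test files.

# Brute-force 1-nearest-neighbour prediction, written as a plain double loop
# so it can serve as an independent oracle for the package's classifiers and
# scheme arithmetic.
nn_oracle_predict <- function(train_x, train_y, test_x) {
  out <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(train_x))) {
      d <- sum((train_x[j, ] - test_x[i, ])^2)
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    out[i] <- train_y[best_j]
  }
  out
}

# Plain parameter combos reused across tests.
combo_raw <- function(c_penalty = 1) {
  list(use_pca = FALSE, variance_threshold = 0.7, c_penalty = c_penalty)
}

grid_one_combo <- function() {
  g <- default_grid(c_values = 1, use_pca = FALSE)
  g
}

# Two far-separated Gaussian-ish clouds: any sensible classifier scores 1.0.
separable_clouds <- function(n_per_class = 10, n_features = 3, seed = 1) {
  withr::with_seed(seed, {
    x0 <- matrix(runif(n_per_class * n_features), n_per_class, n_features)
    x1 <- matrix(runif(n_per_class * n_features) + 10, n_per_class, n_features)
    ct_dataset(rbind(x0, x1), rep(c(0L, 1L), each = n_per_class))
  })
}

# A classifier that records, for every predict() call, the row ids of its
# training set and of the scored samples.  fit_model() keeps row names
# attached through standardization and PCA, so these ids are the original
# sample identities; the leakage audit asserts the two id sets are disjoint.
recording_classifier <- function(log_env) {
  log_env$calls <- list()
  list(
    name = "recording-1nn",
    fit = function(x, y, params) {
      list(x = x, y = as.integer(y), train_ids = rownames(x))
    },
    predict = function(object, x) {
      log_env$calls[[length(log_env$calls) + 1L]] <-
        list(train_ids = object$train_ids, test_ids = rownames(x))
      nn_oracle_predict(object$x, object$y, x)
    }
  )
}
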