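#' Candidate-model grid
#'
#' The search space over which cross-validation selects parameters: the
#' Cartesian product of a preprocessing choice (raw features vs. PCA keeping
#' the smallest number of components that preserves `variance_threshold` of
#' the cumulative variance) and the soft-margin penalty `c` of the classifier.
#' The row order of the grid is part of its contract — ties in mean
#' cross-validation accuracy are broken in favour of the earliest row.
#'
#' @param c_values ascending penalty values (default `c(1e-4, 1e-2, 1)`).
#' @param use_pca preprocessing choices, outer factor of the product
#'   (default `c(FALSE, TRUE)`).
#' @param variance_threshold cumulative-variance fraction preserved by PCA,
#'   in (0, 1] (default 0.70).
#' @return a data.frame of class `ct_grid` with columns `use_pca`,
#'   `variance_threshold`, `c_penalty`; the default has 6 rows.
#' @examples
#' default_grid()
#' @export
default_grid <- function(c_values = c(1e-4, 1e-2, 1),
                         use_pca = c(FALSE, TRUE),
                         variance_threshold = 0.70) {
  stopifnot(length(c_values) >= 1, all(c_values > 0),
            variance_threshold > 0, variance_threshold <= 1)
  g <- expand.grid(c_penalty = as.numeric(c_values),
                   use_pca = as.logical(use_pca),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$use_pca, g$c_penalty), c("use_pca", "c_penalty")]
  g$variance_threshold <- variance_threshold
  g <- g[c("use_pca", "variance_threshold", "c_penalty")]
  if (anyDuplicated(g)) stop("duplicate parameter combinations in grid")
  rownames(g) <- NULL
  class(g) <- c("ct_grid", "data.frame")
  g
}

grid_combo <- function(grid, i) {
  as.list(grid[i, , drop = FALSE])
}

format_combo <- function(combo) {
  if (is.null(combo)) return(NA_character_)
  paste0(if (isTRUE(combo$use_pca)) {
    paste0("pca@", format(combo$variance_threshold))
  } else "raw",
  ",c=", format(combo$c_penalty))
}

#' Number of principal components preserving a variance fraction
#'
#' Returns the smallest `m` such that the first `m` explained-variance ratios
#' sum to at least `threshold`; if even the full set falls short of the
#' threshold (ratios need not sum to 1), all components are kept.
#'
#' @param variance_ratios non-negative ratios in descending order.
#' @param threshold target cumulative fraction, in (0, 1].
#' @return integer component count, at least 1.
#' @examples
#' pca_component_count(c(0.5, 0.3, 0.2), 0.70) # 2
#' @export
pca_component_count <- function(variance_ratios, threshold) {
  if (length(variance_ratios) == 0) stop("`variance_ratios` is empty")
  stopifnot(all(variance_ratios >= 0), threshold > 0, threshold <= 1)
  if (any(diff(variance_ratios) > 1e-12)) {
    stop("`variance_ratios` must be sorted in descending order")
  }
  cum <- cumsum(variance_ratios)
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) length(variance_ratios) else m
}

#' Pluggable classifiers
#'
#' Every scheme trains models through a classifier object: a list with a
#' `fit(x, y, params)` function returning an opaque fitted object and a
#' `predict(object, x)` function returning integer 0/1 labels.  The default is
#' a soft-margin SVM with a radial-basis-function kernel (`e1071::svm`,
#' `cost = params$c_penalty`, bandwidth `gamma = 1/n_features` on
#' standardized features).  `one_nn_classifier` is a deterministic
#' 1-nearest-neighbour predictor (Euclidean distance, first-index tie-break)
#' whose behaviour can be enumerated by hand; the test suite uses it as an
#' independent oracle for the scheme-level contracts.
#'
#' @param kernel kernel name passed to [e1071::svm()] (default `"radial"`).
#' @return a classifier object.
#' @export
svm_classifier <- function(kernel = "radial") {
  list(
    name = paste0("svm-", kernel),
    fit = function(x, y, params) {
      e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = kernel,
                 cost = params$c_penalty, scale = FALSE)
    },
    predict = function(object, x) {
      as.integer(as.character(predict(object, x)))
    }
  )
}

#' @rdname svm_classifier
#' @export
one_nn_classifier <- function() {
  list(
    name = "1nn",
    fit = function(x, y, params) list(x = x, y = as.integer(y)),
    predict = function(object, x) {
      tx <- t(object$x)
      vapply(seq_len(nrow(x)), function(i) {
        d2 <- colSums((tx - x[i, ])^2)
        object$y[which.min(d2)]
      }, integer(1))
    }
  )
}

#' Fit a model for one parameter combination
#'
#' Standardizes features to zero mean and unit variance using statistics of
#' the training partition only, optionally projects onto the principal
#' components retaining `variance_threshold` of the variance (PCA fitted on
#' the training partition only — evaluation data never influence the
#' transform), and fits the classifier with the combo's penalty.  A training
#' set containing a single class yields a constant predictor of that class,
#' flagged as a fallback, so that small-sample sweeps always complete.
#'
#' @param train a [ct_dataset()] with at least one sample.
#' @param params one grid row as a list: `use_pca`, `variance_threshold`,
#'   `c_penalty`.
#' @param classifier a classifier object, see [svm_classifier()].
#' @return an object of class `ct_model`.
#' @export
fit_model <- function(train, params, classifier = svm_classifier()) {
  stopifnot(inherits(train, "ct_dataset"))
  if (n_samples(train) < 1) stop("empty training set")
  classes <- unique(train$labels)
  if (length(classes) < 2) {
    return(structure(
      list(constant = classes[[1]], fallback = TRUE, params = params,
           n_input_features = n_features(train), n_components = 0L,
           train_ids = rownames(train$features)),
      class = "ct_model"
    ))
  }
  x <- train$features
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- scale(x, center = center, scale = scale_)
  rotation <- NULL
  m <- 0L
  if (isTRUE(params$use_pca)) {
    pc <- prcomp(xs, center = FALSE, scale. = FALSE)
    ratios <- pc$sdev^2 / sum(pc$sdev^2)
    m <- pca_component_count(ratios, params$variance_threshold)
    rotation <- pc$rotation[, seq_len(m), drop = FALSE]
    xs <- xs %*% rotation
  }
  fitted <- classifier$fit(xs, train$labels, params)
  structure(
    list(classifier = classifier, fitted = fitted,
         center = center, scale = scale_, rotation = rotation,
         fallback = FALSE, params = params,
         n_input_features = n_features(train), n_components = m,
         train_ids = rownames(train$features)),
    class = "ct_model"
  )
}

#' @export
print.ct_model <- function(x, ...) {
  if (x$fallback) {
    cat("<ct_model> constant predictor of class", x$constant,
        "(single-class training set)\n")
  } else {
    cat("<ct_model>", x$classifier$name, "|", format_combo(x$params),
        if (x$n_components > 0) paste0("| ", x$n_components, " PCs"), "\n")
  }
  invisible(x)
}

#' @export
predict.ct_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "ct_dataset")) newdata$features else newdata
  if (ncol(x) != object$n_input_features) {
    stop("feature dimensionality mismatch: model expects ",
         object$n_input_features, ", got ", ncol(x))
  }
  if (object$fallback) {
    return(structure(rep(object$constant, nrow(x)), names = rownames(x)))
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  if (!is.null(object$rotation)) xs <- xs %*% object$rotation
  p <- object$classifier$predict(object$fitted, xs)
  structure(as.integer(p), names = rownames(x))
}

#' Classification accuracy on a test set
#'
#' @param model a `ct_model`.
#' @param test a non-empty [ct_dataset()] of the training dimensionality.
#' @return fraction of test samples predicted correctly, in \[0, 1\].
#' @export
model_accuracy <- function(model, test) {
  stopifnot(inherits(test, "ct_dataset"))
  if (n_samples(test) < 1) stop("empty test set")
  mean(predict(model, test) == test$labels)
}
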