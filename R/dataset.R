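#' Labeled two-class dataset
#'
#' The universal input of every evaluation scheme: a numeric feature matrix
#' with one binary label per row.  Labels are stored internally as integers
#' 0/1; the original label values (e.g. strings from a CSV) are kept in the
#' `label_levels` field so that writing a dataset back out round-trips them.
#' Row names are stable sample identifiers: subsetting, subsampling and label
#' permutation all preserve them, which is what lets the test suite audit that
#' no sample is ever scored by a model that was trained on it.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels vector with exactly two distinct values (or fewer than two
#'   only for single-sample edge cases); mapped to 0/1 by first occurrence.
#' @param label_levels optional length-2 character vector naming the values
#'   that 0 and 1 stand for.
#' @return an object of class `ct_dataset` with fields `features`, `labels`
#'   (integer 0/1) and `label_levels`.
#' @examples
#' d <- ct_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' d
#' @export
ct_dataset <- function(features, labels, label_levels = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != length(labels)) {
    stop("`features` has ", nrow(features), " rows but `labels` has length ",
         length(labels))
  }
  if (!all(is.finite(features))) stop("`features` contains non-finite values")
  if (is.null(rownames(features))) {
    rownames(features) <- sprintf("s%d", seq_len(nrow(features)))
  }
  if (is.null(label_levels)) {
    label_levels <- as.character(unique(labels))
    if (length(label_levels) > 2) {
      stop("more than two distinct labels: ",
           paste(utils::head(label_levels, 5), collapse = ", "))
    }
  }
  lab <- match(as.character(labels), label_levels) - 1L
  if (anyNA(lab)) stop("labels outside `label_levels`")
  names(lab) <- rownames(features)
  structure(
    list(features = features, labels = lab,
         label_levels = as.character(label_levels)),
    class = "ct_dataset"
  )
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat("<ct_dataset> ", nrow(x$features), " samples x ", ncol(x$features),
      " features\n", sep = "")
  tab <- table(factor(x$labels, levels = c(0L, 1L)))
  cat("  class counts: ", x$label_levels[1], "=", tab[[1]],
      if (length(x$label_levels) > 1) paste0(", ", x$label_levels[2], "=", tab[[2]]),
      "\n", sep = "")
  invisible(x)
}

#' Number of samples / features in a dataset
#' @param dataset a [ct_dataset()].
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$features)

#' @rdname n_samples
#' @export
n_features <- function(dataset) ncol(dataset$features)

#' Subset a dataset by sample index
#'
#' Keeps sample ids (row names) and the label mapping.
#' @param x a [ct_dataset()].
#' @param i integer or logical row index.
#' @return a [ct_dataset()].
#' @export
`[.ct_dataset` <- function(x, i) dataset_slice(x, i)

# Subset by row index, keeping ids and label mapping.
dataset_slice <- function(dataset, idx) {
  ct_dataset(dataset$features[idx, , drop = FALSE],
             dataset$label_levels[dataset$labels[idx] + 1L],
             label_levels = dataset$label_levels)
}

# Replace the label vector (used by the permutation test); ids stay attached
# to the rows, not to the labels.
dataset_relabel <- function(dataset, new_labels) {
  out <- dataset
  lab <- as.integer(new_labels)
  names(lab) <- rownames(dataset$features)
  out$labels <- lab
  out
}

#' Generate the linearly inseparable two-class benchmark
#'
#' Draws `4 * per_subgroup` samples with `n_features` features, all uniform on
#' \[0, 1\], then shifts selected dimensions by `offset` so that each class is a
#' mixture of two subgroups: class A is {no shift} and {dims 1 and 2 shifted},
#' class B is {dim 1 shifted} and {dim 2 shifted}.  In the first two dimensions
#' the class regions interleave like an XOR pattern, so no linear boundary
#' separates them, but the structure is learnable by a nonlinear classifier.
#' Rows are shuffled before return so that contiguous subsets are still random.
#'
#' @param per_subgroup samples per subgroup (default 2000, giving the reference
#'   size of 8000).
#' @param n_features number of features, at least 2 (default 6); dimensions
#'   3 and up are pure uniform noise.
#' @param offset shift added to the selected dimensions (default 0.8).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a [ct_dataset()] with `4 * per_subgroup` rows, balanced classes.
#' @examples
#' d <- generate_simulated(per_subgroup = 25, seed = 1)
#' table(d$labels)
#' @export
generate_simulated <- function(per_subgroup = 2000, n_features = 6,
                               offset = 0.8, seed = 1) {
  if (!is.numeric(per_subgroup) || per_subgroup < 1) {
    stop("`per_subgroup` must be a positive integer")
  }
  if (!is.numeric(n_features) || n_features < 2) {
    stop("`n_features` must be at least 2 (the offsets touch dimensions 1 and 2)")
  }
  per <- as.integer(per_subgroup)
  f <- as.integer(n_features)
  n <- 4L * per
  local_seed(seed, {
    x <- matrix(runif(n * f), n, f)
    sub <- function(i) ((i - 1L) * per + 1L):(i * per)
    # class A: subgroup 1 untouched, subgroup 2 shifted in dims 1 and 2
    x[sub(2L), 1:2] <- x[sub(2L), 1:2] + offset
    # class B: subgroup 3 shifted in dim 1, subgroup 4 in dim 2
    x[sub(3L), 1] <- x[sub(3L), 1] + offset
    x[sub(4L), 2] <- x[sub(4L), 2] + offset
    y <- rep(c(0L, 1L), each = 2L * per)
    ord <- sample.int(n)
    rownames(x) <- sprintf("s%d", seq_len(n))
    ct_dataset(x[ord, , drop = FALSE], y[ord], label_levels = c("0", "1"))
  })
}

#' Generate the random-label null benchmark
#'
#' All features uniform on \[0, 1\] and every label an independent fair coin
#' flip, so labels carry no information about features.  Used to check that an
#' evaluation pipeline reports chance accuracy and a false-positive rate at
#' the nominal alpha.
#'
#' @param n_samples number of samples (default 10000).
#' @param n_features number of features (default 20).
#' @param seed integer seed.
#' @return a [ct_dataset()].
#' @examples
#' generate_random(n_samples = 50, n_features = 4, seed = 2)
#' @export
generate_random <- function(n_samples = 10000, n_features = 20, seed = 1) {
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("`n_samples` must be at least 2")
  }
  if (!is.numeric(n_features) || n_features < 1) {
    stop("`n_features` must be positive")
  }
  n <- as.integer(n_samples)
  f <- as.integer(n_features)
  local_seed(seed, {
    x <- matrix(runif(n * f), n, f)
    rownames(x) <- sprintf("s%d", seq_len(n))
    y <- as.integer(runif(n) < 0.5)
    ct_dataset(x, y, label_levels = c("0", "1"))
  })
}

#' Stratified subsample without replacement
#'
#' Draws `n` samples from a reference dataset, preserving the class proportions
#' as closely as integer counts allow (largest-remainder rounding) and
#' guaranteeing at least one sample of each class.  This is how the sweep
#' experiments draw their per-replicate working sets from a large reference.
#'
#' @param dataset a [ct_dataset()].
#' @param n subsample size, `2 <= n <= n_samples(dataset)`.
#' @param seed integer seed.
#' @return a [ct_dataset()] of `n` rows.
#' @export
subsample_dataset <- function(dataset, n, seed) {
  N <- n_samples(dataset)
  if (n > N) stop("requested subsample of ", n, " from a reference of ", N)
  if (n < 2) stop("`n` must be at least 2")
  idx_by_class <- split(seq_len(N), dataset$labels)
  if (length(idx_by_class) < 2) stop("reference dataset has a single class")
  props <- vapply(idx_by_class, length, 1L) / N
  base <- floor(n * props)
  rem <- n - sum(base)
  frac <- n * props - base
  if (rem > 0) {
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[bump] <- base[bump] + 1
  }
  base <- pmax(base, 1)
  while (sum(base) > n) { # n >= 2 guarantees this terminates validly
    i <- which.max(base)
    base[i] <- base[i] - 1
  }
  local_seed(seed, {
    take <- unlist(mapply(function(ix, k) sample(ix, k),
                          idx_by_class, base, SIMPLIFY = FALSE))
    dataset_slice(dataset, sample(take)) # shuffle row order too
  })
}

#' Read / write a labeled dataset as CSV
#'
#' The on-disk format is a plain comma-separated file with a header row, one
#' column named `label` and all remaining columns numeric features.  Label
#' values may be arbitrary (two distinct values); they are mapped to 0/1 by
#' order of first occurrence, and `write_dataset_csv` writes the original
#' values back, so a write/read cycle round-trips labels exactly and features
#' to text precision.
#'
#' @param path file path.
#' @return `read_dataset_csv` returns a [ct_dataset()];
#'   `write_dataset_csv` invisibly returns `path`.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) {
    stop("CSV has no `label` column: ", path)
  }
  lab_raw <- as.character(df[["label"]])
  feat_cols <- setdiff(names(df), "label")
  if (length(feat_cols) == 0) stop("CSV has no feature columns: ", path)
  for (cn in feat_cols) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop("non-numeric feature value in column `", cn, "`, row ",
           ifelse(is.na(bad), "?", bad))
    }
  }
  levels <- unique(lab_raw)
  if (length(levels) != 2) {
    stop("expected exactly 2 distinct labels, found ", length(levels))
  }
  x <- as.matrix(df[feat_cols])
  ct_dataset(x, lab_raw, label_levels = levels)
}

#' @rdname read_dataset_csv
#' @param dataset a [ct_dataset()] to write.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "ct_dataset"))
  df <- data.frame(label = dataset$label_levels[dataset$labels + 1L],
                   dataset$features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
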