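#' One Monte-Carlo replicate of a sweep cell
#'
#' Draws a stratified subsample of the requested size from the reference
#' dataset, runs one evaluation scheme on it and (optionally) attaches the
#' permutation significance test.  The replicate is a pure function of
#' `(master_seed, condition, scheme, rep_index)`: the seed of every stage is
#' derived from those four values, so any single replicate of a sweep can be
#' reproduced in isolation.
#'
#' @param reference the reference [ct_dataset()] replicates are drawn from.
#' @param scheme scheme name, see [run_scheme()].
#' @param rep_index replicate number (1-based).
#' @param n subsample size; `NULL` uses the full reference.
#' @param test_fraction held-out fraction for the split-based schemes.
#' @param grid,k_select,k_test,k_outer,k_inner,classifier see [run_scheme()].
#' @param significance attach a permutation test? (default `TRUE`).
#' @param n_permutations,alpha,mode,rule see [permutation_significance()].
#' @param master_seed integer master seed of the whole sweep.
#' @return a `ct_result` with `condition`, `rep_index` and `n_used` fields set.
#' @export
run_one <- function(reference, scheme, rep_index, n = NULL,
                    test_fraction = 0.5, grid = default_grid(),
                    k_select = 5, k_test = 5, k_outer = 5, k_inner = 5,
                    significance = TRUE, n_permutations = 199, alpha = 0.05,
                    mode = "full_rerun", rule = "randomized",
                    master_seed = 1, classifier = svm_classifier()) {
  condition <- if (!is.null(n)) paste0("n=", n) else
    paste0("test_fraction=", format(test_fraction))
  seed_r <- mix_seed(master_seed, scheme, condition, rep_index)
  d <- if (!is.null(n) && n < n_samples(reference)) {
    subsample_dataset(reference, n, mix_seed(seed_r, "subsample"))
  } else {
    reference
  }
  res <- if (significance) {
    permutation_significance(d, scheme, grid, test_fraction, k_select, k_test,
                             k_outer, k_inner, n_permutations, alpha,
                             mode = mode, rule = rule, seed = seed_r,
                             classifier = classifier)
  } else {
    run_scheme(d, scheme, grid, test_fraction, k_select, k_test, k_outer,
               k_inner, seed = mix_seed(seed_r, "perm", 0),
               classifier = classifier)
  }
  res$condition <- condition
  res$rep_index <- as.integer(rep_index)
  res$n_used <- n_samples(d)
  res
}

result_log_row <- function(res) {
  data.frame(
    condition = res$condition, scheme = res$scheme, rep = res$rep_index,
    accuracy = res$accuracy, p_geq = res$p_geq, p_gt = res$p_gt,
    significant = res$significant, randomized = res$randomized,
    best_combo = format_combo(if (is.null(res$selection)) NULL else
      res$selection$best),
    fallback_count = res$fallback_count,
    stringsAsFactors = FALSE
  )
}

aggregate_log <- function(log) {
  cells <- unique(log[c("condition", "scheme")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- log[log$condition == cells$condition[i] &
                 log$scheme == cells$scheme[i], ]
    n_reps <- nrow(sub)
    prop_sig <- if (all(is.na(sub$significant))) NA_real_ else
      mean(sub$significant)
    data.frame(
      condition = cells$condition[i], scheme = cells$scheme[i],
      n_reps = n_reps,
      mean_accuracy = mean(sub$accuracy),
      se_accuracy = sd(sub$accuracy) / sqrt(n_reps),
      proportion_significant = prop_sig,
      se_significant = if (is.na(prop_sig)) NA_real_ else
        sqrt(prop_sig * (1 - prop_sig) / n_reps),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

run_sweep <- function(reference, conditions, schemes, n_reps, fixed, ...) {
  logs <- list()
  for (cond in conditions) {
    for (scheme in schemes) {
      for (r in seq_len(n_reps)) {
        args <- c(list(reference = reference, scheme = scheme, rep_index = r),
                  cond, fixed, list(...))
        logs[[length(logs) + 1L]] <- result_log_row(do.call(run_one, args))
      }
    }
  }
  log <- do.call(rbind, logs)
  structure(list(summary = aggregate_log(log), log = log), class = "ct_sweep")
}

#' @export
print.ct_sweep <- function(x, ...) {
  cat("<ct_sweep> ", nrow(x$log), " replicates over ", nrow(x$summary),
      " cells\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Sweep over total data-set size at a fixed test fraction
#'
#' For each size in `sizes` and each scheme, runs `n_reps` independent
#' replicates ([run_one()]) and aggregates mean accuracy and the proportion of
#' significant results with their Monte-Carlo standard errors.  This is the
#' design used to show that more data raise both accuracy and the probability
#' of a significant result, and (on the random-label reference) that the
#' false-positive rate stays at alpha.
#'
#' @param reference reference [ct_dataset()].
#' @param sizes vector of total subsample sizes.
#' @param schemes character vector of scheme names.
#' @param n_reps replicates per cell (default 100).
#' @param test_fraction fixed held-out fraction (default 0.5).
#' @param ... further arguments to [run_one()] (e.g. `n_permutations`,
#'   `mode`, `master_seed`, `classifier`, `significance = FALSE`).
#' @return a `ct_sweep`: list with `summary` (one row per size x scheme) and
#'   `log` (one row per replicate).
#' @export
sweep_dataset_size <- function(reference, sizes,
                               schemes = c("cv_and_test", "cv_and_crosstest",
                                           "nested_cv"),
                               n_reps = 100, test_fraction = 0.5, ...) {
  stopifnot(length(sizes) >= 1, n_reps >= 1)
  conditions <- lapply(sizes, function(n) list(n = n))
  run_sweep(reference, conditions, schemes, n_reps,
            fixed = list(test_fraction = test_fraction), ...)
}

#' Sweep over the test-set fraction at a fixed data-set size
#'
#' Varies the held-out fraction (the canonical sweep runs 10% to 90%) at
#' fixed total `n`.  Only the two split-based schemes are
#' admissible: nested cross-validation has no test fraction, and requesting it
#' here is a configuration error.
#'
#' @param reference reference [ct_dataset()].
#' @param test_fractions vector of fractions in (0, 1).
#' @param schemes subset of `c("cv_and_test", "cv_and_crosstest")`.
#' @param n fixed subsample size (default 100).
#' @param n_reps replicates per cell (default 100).
#' @param ... further arguments to [run_one()].
#' @return a `ct_sweep`.
#' @export
sweep_test_fraction <- function(reference, test_fractions,
                                schemes = c("cv_and_test", "cv_and_crosstest"),
                                n = 100, n_reps = 100, ...) {
  stopifnot(length(test_fractions) >= 1, n_reps >= 1)
  if ("nested_cv" %in% schemes) {
    stop("nested_cv has no test-set fraction; it cannot be part of a ",
         "test-fraction sweep")
  }
  conditions <- lapply(test_fractions, function(f) list(test_fraction = f))
  run_sweep(reference, conditions, schemes, n_reps, fixed = list(n = n), ...)
}

#' Read a sweep configuration file
#'
#' Accepts YAML (`.yaml`/`.yml`) or JSON (`.json`).  Keys mirror the arguments
#' of the sweep functions; see the CLI script
#' (`system.file("cli", "crosstesting.R", package = "crosstesting")`) for the
#' full set.
#'
#' @param path configuration file path.
#' @return a named list.
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension `.", ext, "` (use YAML or JSON)")
  }
}
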