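test_that("run_one is a pure function of (master_seed, condition, scheme, rep)", {
  ref <- generate_random(400, 3, seed = 1)
  a <- run_one(ref, "cv_and_crosstest", rep_index = 2, n = 30,
               n_permutations = 9, master_seed = 7,
               classifier = one_nn_classifier())
  b <- run_one(ref, "cv_and_crosstest", rep_index = 2, n = 30,
               n_permutations = 9, master_seed = 7,
               classifier = one_nn_classifier())
  expect_identical(a, b)
  expect_equal(a$n_used, 30L)
  expect_gte(a$p_geq, 1 / 10)

  nested <- run_one(ref, "nested_cv", rep_index = 1, n = 20,
                    significance = FALSE, master_seed = 7,
                    classifier = one_nn_classifier())
  expect_null(nested$selection)
  expect_true(nested$accuracy >= 0 && nested$accuracy <= 1)
})

test_that("sweep aggregates are exactly recomputable from the replicate log", {
  ref <- generate_simulated(per_subgroup = 100, seed = 2)
  sw <- sweep_dataset_size(ref, sizes = c(24, 40),
                           schemes = c("cv_and_test", "cv_and_crosstest"),
                           n_reps = 4, n_permutations = 9, master_seed = 3,
                           classifier = one_nn_classifier())
  expect_equal(nrow(sw$summary), 4L)
  expect_equal(nrow(sw$log), 16L)
  for (i in seq_len(nrow(sw$summary))) {
    cell <- sw$summary[i, ]
    sub <- sw$log[sw$log$condition == cell$condition &
                    sw$log$scheme == cell$scheme, ]
    expect_equal(cell$mean_accuracy, mean(sub$accuracy))
    expect_equal(cell$proportion_significant, mean(sub$significant))
    expect_equal(cell$n_reps, nrow(sub))
  }
  # single replicate: proportions are 0 or 1 by construction
  one <- sweep_test_fraction(ref, test_fractions = 0.5,
                             schemes = "cv_and_test", n = 20, n_reps = 1,
                             n_permutations = 9, master_seed = 4,
                             classifier = one_nn_classifier())
  expect_true(one$summary$proportion_significant %in% c(0, 1))
})

test_that("test-fraction sweeps refuse nested CV", {
  ref <- generate_random(200, 2, seed = 5)
  expect_error(
    sweep_test_fraction(ref, test_fractions = c(0.3, 0.5),
                        schemes = c("cv_and_test", "nested_cv")),
    "no test-set fraction")
})

test_that("YAML and JSON sweep configs parse to the same settings", {
  cfg <- list(reference = "random", reference_n = 200, n_features = 4,
              sizes = c(20, 40), n_reps = 2, n_permutations = 9,
              master_seed = 1)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  jpath <- withr::local_tempfile(fileext = ".json")
  yaml::write_yaml(cfg, ypath)
  jsonlite::write_json(cfg, jpath, auto_unbox = TRUE)
  y <- read_sweep_config(ypath)
  j <- read_sweep_config(jpath)
  for (k in names(cfg)) expect_equal(y[[k]], j[[k]])
  expect_error(read_sweep_config("nope.toml"), "not found")
  bad <- withr::local_tempfile(fileext = ".toml")
  writeLines("x", bad)
  expect_error(read_sweep_config(bad), "unsupported")
})

test_that("the CLI generates, runs and fails loudly", {
  cli <- system.file("cli", "crosstesting.R", package = "crosstesting")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "d.csv")

  gen <- system2(rscript, c(cli, "generate", "--kind", "random", "--n", "30",
                            "--features", "3", "--seed", "1", "--out", csv),
                 stdout = TRUE, stderr = TRUE, env = env)
  expect_equal(attr(gen, "status"), NULL)
  expect_true(file.exists(csv))

  run_args <- c(cli, "run", "--scheme", "cv_and_crosstest", "--data", csv,
                "--seed", "3", "--permutations", "9")
  out1 <- system2(rscript, run_args, stdout = TRUE, stderr = FALSE, env = env)
  out2 <- system2(rscript, run_args, stdout = TRUE, stderr = FALSE, env = env)
  expect_identical(out1, out2)
  expect_match(out1[1], "accuracy")
  expect_equal(length(out1), 2L) # header + one TSV row

  bad <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE,
            env = env))
  expect_false(is.null(attr(bad, "status")))
  missing_cfg <- suppressWarnings(
    system2(rscript, c(cli, "sweep", "--config", "missing.yaml"),
            stdout = TRUE, stderr = TRUE, env = env))
  expect_false(is.null(attr(missing_cfg, "status")))
})
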