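# A modest treatment grid keeps the full-study tests fast; the grid still
# spans no-preprocessing, scatter-corrected and derivative recipes.
small_grid <- c("None 0,0,1,1", "SNV 1,4,4,1", "Detrend only 1,4,4,1")

test_that("the calibration study emits one descriptor row per parameter", {
  ds <- generate_dataset(synthetic_config(seed = 21))
  study <- run_calibration_study(ds$spectra, ds$reference, ds$split,
                                 treatments = small_grid, max_factors = 10,
                                 seed = 3)
  expect_equal(nrow(study$calibration_table), 11)
  expect_equal(names(study$calibration_table),
               c("Variable", "Math Treatment", "N", "Mean", "SD", "Est.Min",
                 "Est.Max", "SEC", "RSQ", "SECV", "RPD"))
  expect_equal(nrow(study$validation_table), 11)
  expect_equal(names(study$validation_table),
               c("Variable", "Mean Residual", "RMSE", "p"))
  # recovery tiers: at least 8 of 11 parameters reach RPD >= 1.5
  expect_gte(sum(study$calibration_table$RPD >= 1.5), 8)
  # removed-sample bookkeeping is consistent with retained N
  for (par in study$calibration_table$Variable) {
    rem <- study$removed[[par]]
    expect_equal(study$calibration_table$N[study$calibration_table$Variable == par],
                 84 - length(rem$H) - length(rem$T))
  }
  expect_error(
    run_calibration_study(ds$spectra, ds$reference, ds$split,
                          parameters = "sucrose", treatments = small_grid),
    "sucrose")
})

test_that("disabled screening retains the full calibration group", {
  ds <- generate_dataset(synthetic_config(seed = 22))
  study <- run_calibration_study(ds$spectra, ds$reference, ds$split,
                                 parameters = c("moisture", "phenols"),
                                 treatments = "SNV 1,4,4,1",
                                 h_threshold = Inf, t_threshold = Inf,
                                 seed = 3)
  expect_true(all(study$calibration_table$N == 84))
})

test_that("the discriminant study reproduces the published table shapes", {
  ds <- generate_dataset(synthetic_config(seed = 23))
  study <- run_discriminant_study(ds$reference, ds$pollen, ds$labels)
  # p = 15 features: 11 physicochemical + 4 main pollen types
  expect_equal(ncol(study$features), 15)
  expect_equal(length(study$model$eigenvalues), 5)
  expect_equal(study$diagnostics$df, c(75, 56, 39, 24, 11))
  # confusion rows sum to the configured group sizes
  cm <- study$confusion$matrix
  expect_equal(unname(rowSums(cm)[c("heather", "chestnut", "eucalyptus",
                                    "blackberry", "honeydew", "multifloral")]),
               c(5, 22, 9, 10, 18, 36))
  # the synthetic world separates types: overall resubstitution >= 80%
  expect_gte(study$confusion$overall_correct_pct, 80)
  # determinism: identical rerun
  study2 <- run_discriminant_study(ds$reference, ds$pollen, ds$labels)
  expect_identical(study$diagnostics, study2$diagnostics)
  expect_identical(study$confusion$matrix, study2$confusion$matrix)
})

test_that("calibration reports are regenerable bit-identically from the seed", {
  ds <- generate_dataset(synthetic_config(seed = 24))
  run <- function() run_calibration_study(
    ds$spectra, ds$reference, ds$split, parameters = "pfund",
    treatments = small_grid, seed = 7)
  expect_identical(run()$calibration_table, run()$calibration_table)
})

test_that("the CLI simulates, types pollen and writes reports", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "data")
  expect_output(honeynir_cli(c("simulate", "--out", out, "--seed", "9",
                               "--n-samples", "40")),
                "wrote synthetic dataset")
  expect_true(file.exists(file.path(out, "spectra.csv")))
  lab <- read.csv(file.path(out, "labels.csv"))
  expect_equal(nrow(lab), 40)
  out2 <- file.path(dir, "typed")
  expect_output(honeynir_cli(c("pollen-type", "--data", out, "--out", out2)),
                "typed 40 samples")
  types <- read.csv(file.path(out2, "honey_types.csv"))
  expect_true(all(types$honey_type %in%
                  c("heather", "chestnut", "eucalyptus", "blackberry",
                    "honeydew", "multifloral")))
  # lda subcommand writes the diagnostics and confusion CSVs
  out3 <- file.path(dir, "lda")
  honeynir_cli(c("lda", "--data", out, "--out", out3))
  expect_true(file.exists(file.path(out3, "lda_diagnostics.csv")))
  expect_true(file.exists(file.path(out3, "lda_confusion.csv")))
})
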