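test_that("generation is byte-identical for a fixed config and seed", {
  cfg <- synthetic_config(n_samples = 30, seed = 99,
                          honey_type_counts = c(heather = 5, chestnut = 5,
                                                eucalyptus = 5, blackberry = 5,
                                                honeydew = 5, multifloral = 5))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- generate_dataset(synthetic_config(n_samples = 30, seed = 100,
                                          honey_type_counts = cfg$honey_type_counts))
  expect_false(identical(d1$spectra$values, d3$spectra$values))
})

test_that("noiseless single-band spectra are the exact linear mixture", {
  cons <- data.frame(parameter = "moisture", mean = 17.9, sd = 0,
                     min = 17.9, max = 17.9)
  band <- list(moisture = matrix(c(1450, 40, 0.05), 1,
                                 dimnames = list(NULL, c("center", "width", "amplitude"))))
  cfg <- synthetic_config(
    n_samples = 2, honey_type_counts = c(multifloral = 2),
    constituents = cons,
    type_offsets = matrix(0, 1, 1, dimnames = list("multifloral", "moisture")),
    band_library = band, scatter_sd = 0, offset_sd = 0, baseline_sd = 0,
    noise_sd = 0, seed = 5)
  ds <- generate_dataset(cfg)
  wl <- ds$spectra$wavelengths
  expected <- 17.9 * 0.05 * exp(-(wl - 1450)^2 / (2 * 40^2))
  expect_equal(unname(ds$spectra$values[1, ]), expected, tolerance = 1e-12)
  expect_equal(ds$reference$moisture, c(17.9, 17.9))
})

test_that("pooled constituent means and ranges honor the configuration", {
  cfg <- synthetic_config(seed = 1)
  ds <- generate_dataset(cfg)
  # moisture is type-neutral: pooled mean within 3 standard errors of 17.9
  se <- 1.1 * cfg$within_sd_scale / sqrt(100)
  expect_lt(abs(mean(ds$reference$moisture) - 17.9), 3 * se)
  # all values inside the configured truncation ranges
  for (j in seq_len(nrow(cfg$constituents))) {
    v <- ds$reference[[cfg$constituents$parameter[j]]]
    expect_true(all(v >= cfg$constituents$min[j] - 1e-9))
    expect_true(all(v <= cfg$constituents$max[j] + 1e-9))
  }
  # the three tables share the identical ordered sample list
  expect_identical(ds$reference$sample_id, ds$spectra$sample_ids)
  expect_identical(ds$pollen$sample_id, ds$spectra$sample_ids)
  expect_identical(names(ds$labels), ds$spectra$sample_ids)
})

test_that("pollen profiles are compositional with configured type means", {
  cfg <- synthetic_config(seed = 2)
  set.seed(2)
  prof <- generate_pollen_profiles(cfg, rep("eucalyptus", 500))
  mat <- as.matrix(prof[, -1])
  expect_true(all(mat >= 0))
  expect_true(all(abs(rowSums(mat) - 100) < 0.01))
  # Dirichlet mean check: Eucalyptus share over 500 draws within 2 SE of 72.8
  p <- 0.728
  se_draw <- sqrt(p * (1 - p) / (cfg$pollen_precision + 1)) * 100
  expect_lt(abs(mean(mat[, "Eucalyptus"]) - 72.8), 2 * se_draw / sqrt(500))
  # degenerate Dirichlet: one concentration dominating -> main pollen ~100%
  cfg2 <- cfg
  cfg2$pollen_dirichlet$eucalyptus[] <- 1e-4
  cfg2$pollen_dirichlet$eucalyptus["Eucalyptus"] <- 100
  set.seed(3)
  prof2 <- generate_pollen_profiles(cfg2, rep("eucalyptus", 20))
  expect_true(all(prof2$Eucalyptus > 99.9))
  expect_error(generate_pollen_profiles(cfg, c("clover")), "unknown honey type")
})

test_that("the calibration/validation split is a stratified partition", {
  cfg <- synthetic_config(seed = 4)
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$split == "calibration"), 84)
  expect_equal(sum(ds$split == "validation"), 16)
  expect_setequal(names(ds$split), ds$spectra$sample_ids)
  # stratification: every type appears in calibration
  tab <- table(ds$labels, ds$split)
  expect_true(all(tab[, "calibration"] > 0))
  # small-n exact split
  cfg2 <- synthetic_config(n_samples = 4, calibration_fraction = 0.5,
                           honey_type_counts = c(multifloral = 4), seed = 6)
  ds2 <- generate_dataset(cfg2)
  expect_equal(as.vector(table(ds2$split)), c(2, 2))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(n_samples = 99,
                                honey_type_counts = c(multifloral = 100)),
               "honey_type_counts")
  expect_error(synthetic_config(calibration_fraction = 1.2),
               "calibration_fraction")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  bad_band <- default_band_library("moisture")
  bad_band$moisture[1, "center"] <- 2500
  expect_error(synthetic_config(band_library = bad_band), "band_library")
})

test_that("datasets round-trip through the CSV layout", {
  cfg <- synthetic_config(n_samples = 12, seed = 8,
                          honey_type_counts = c(chestnut = 6, multifloral = 6))
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset_csv(ds, dir)
  sp <- read_spectra_csv(file.path(dir, "spectra.csv"))
  expect_equal(unname(sp$values), unname(ds$spectra$values), tolerance = 1e-10)
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(lab$honey_type, unname(ds$labels))
  expect_equal(sort(unique(lab$split)), c("calibration", "validation"))
})
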