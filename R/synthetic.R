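#' Configuration of the synthetic honey dataset generator
#'
#' Describes a population of honey samples of six botanical types with the
#' statistical structure the calibration and discriminant analyses assume:
#' physicochemical constituents drawn from truncated normals (global
#' means/SDs/ranges matching published reference tables, with per-type mean
#' offsets so darker honeys carry more conductivity, color and phenolics);
#' pollen profiles drawn from per-type Dirichlet distributions; and NIR
#' spectra built as noisy, scatter-distorted linear mixtures of per-
#' constituent Gaussian absorption bands, averaged over replicate scans.
#'
#' @param n_samples total samples (default 100).
#' @param calibration_fraction fraction assigned to the calibration group
#'   (default 0.84, i.e. 84/16).
#' @param honey_type_counts named integer vector over the six types summing
#'   to `n_samples` (defaults heather 5, chestnut 22, eucalyptus 9,
#'   blackberry 10, honeydew 18, multifloral 36).
#' @param constituents data frame `parameter, mean, sd, min, max` of global
#'   constituent distributions (defaults from the reference data of the
#'   calibration set).
#' @param type_offsets matrix (types x parameters) of per-type mean shifts
#'   in global-SD units.
#' @param within_sd_scale within-type SD as a fraction of the global SD
#'   (default 0.6).
#' @param band_library named list: parameter -> matrix with columns
#'   `center`, `width`, `amplitude` of Gaussian absorption bands
#'   (absorbance units per unit of the parameter).
#' @param wavelengths wavelength axis in nm (default 125 evenly spaced
#'   channels over 908-1676 nm, the working range of a 128-pixel portable
#'   detector).
#' @param scatter_sd multiplicative scatter factor SD (per replicate scan).
#' @param offset_sd additive baseline offset SD.
#' @param baseline_sd quadratic baseline coefficient SD.
#' @param noise_sd channel noise SD in absorbance units, per replicate.
#' @param replicate_scans scans averaged per sample (default 3).
#' @param pollen_dirichlet named list: honey type -> named mean-percentage
#'   vector over pollen taxa (summing to 100).
#' @param pollen_precision Dirichlet precision (sum of concentrations;
#'   default 300).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 100,
                             calibration_fraction = 0.84,
                             honey_type_counts = NULL,
                             constituents = NULL,
                             type_offsets = NULL,
                             within_sd_scale = 0.6,
                             band_library = NULL,
                             wavelengths = seq(908, 1676, length.out = 125),
                             scatter_sd = 0.05,
                             offset_sd = 0.02,
                             baseline_sd = 0.01,
                             noise_sd = 0.005,
                             replicate_scans = 3,
                             pollen_dirichlet = NULL,
                             pollen_precision = 300,
                             seed = 1L) {
  if (is.null(honey_type_counts)) {
    base <- c(heather = 5, chestnut = 22, eucalyptus = 9,
              blackberry = 10, honeydew = 18, multifloral = 36)
    if (n_samples == 100) {
      honey_type_counts <- base
    } else {
      # scale the reference composition, largest-remainder rounding
      exact <- base / 100 * n_samples
      cnt <- floor(exact)
      short <- n_samples - sum(cnt)
      if (short > 0) {
        ord <- order(exact - cnt, decreasing = TRUE)
        cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
      }
      honey_type_counts <- cnt
    }
  }
  if (is.null(constituents)) constituents <- default_constituents()
  if (is.null(type_offsets))
    type_offsets <- default_type_offsets(names(honey_type_counts),
                                         constituents$parameter)
  if (is.null(band_library)) band_library <- default_band_library(constituents$parameter)
  if (is.null(pollen_dirichlet)) pollen_dirichlet <- default_pollen_means()

  cfg <- structure(list(
    n_samples = as.integer(n_samples),
    calibration_fraction = calibration_fraction,
    honey_type_counts = honey_type_counts,
    constituents = constituents,
    type_offsets = type_offsets,
    within_sd_scale = within_sd_scale,
    band_library = band_library,
    wavelengths = wavelengths,
    scatter_sd = scatter_sd, offset_sd = offset_sd,
    baseline_sd = baseline_sd, noise_sd = noise_sd,
    replicate_scans = as.integer(replicate_scans),
    pollen_dirichlet = pollen_dirichlet,
    pollen_precision = pollen_precision,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (sum(cfg$honey_type_counts) != cfg$n_samples)
    stop("configuration error: honey_type_counts sums to ",
         sum(cfg$honey_type_counts), ", not n_samples = ", cfg$n_samples)
  if (!(cfg$calibration_fraction > 0 && cfg$calibration_fraction < 1))
    stop("configuration error: calibration_fraction must be in (0, 1)")
  if (any(cfg$constituents$sd < 0))
    stop("configuration error: negative constituent sd")
  for (nm in c("scatter_sd", "offset_sd", "baseline_sd", "noise_sd"))
    if (cfg[[nm]] < 0) stop("configuration error: ", nm, " must be >= 0")
  if (cfg$replicate_scans < 1)
    stop("configuration error: replicate_scans must be >= 1")
  rng <- range(cfg$wavelengths)
  for (par in names(cfg$band_library)) {
    b <- cfg$band_library[[par]]
    if (any(b[, "center"] < rng[1] | b[, "center"] > rng[2]))
      stop("configuration error: band_library center for '", par,
           "' outside the wavelength axis")
  }
  missing_types <- setdiff(names(cfg$honey_type_counts),
                           names(cfg$pollen_dirichlet))
  if (length(missing_types) > 0)
    stop("configuration error: pollen_dirichlet missing type(s) ",
         paste(missing_types, collapse = ", "))
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_samples, " samples (",
      paste(names(x$honey_type_counts), x$honey_type_counts,
            sep = "=", collapse = ", "),
      "), ", length(x$wavelengths), " channels, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Global constituent distributions of the calibration population
# (mean, SD, observed range) for the 11 physicochemical parameters.
default_constituents <- function() {
  data.frame(
    parameter = c("moisture", "ec", "ph", "hmf", "diastase", "pfund",
                  "L", "a", "b", "phenols", "flavonoids"),
    mean = c(17.9, 869.2, 4.2, 0.1, 29.0, 98.2, 69.5, 7.4, 23.1, 126.3, 6.7),
    sd   = c(1.1, 307.6, 0.3, 0.2, 9.3, 31.2, 10.4, 5.2, 9.2, 51.9, 3.2),
    min  = c(15.5, 302.5, 3.7, 0.0, 10.1, 41.0, 51.9, -3.1, 2.8, 36.3, 3.0),
    max  = c(20.6, 1649.5, 4.8, 1.7, 44.0, 150.0, 84.5, 14.6, 36.2, 254.5, 16.7),
    stringsAsFactors = FALSE
  )
}

# Per-type constituent mean shifts in global-SD units. Dark honeys
# (heather, chestnut, honeydew) get higher conductivity, Pfund color and
# phenolics and lower luminance; eucalyptus and blackberry the reverse.
# Moisture is kept type-neutral.
default_type_offsets <- function(types, parameters) {
  m <- matrix(0, length(types), length(parameters),
              dimnames = list(types, parameters))
  set <- function(type, ...) {
    v <- c(...)
    m[type, names(v)] <<- v
  }
  if ("heather" %in% types)
    set("heather", ec = 0.8, ph = 0.2, pfund = 0.8, L = -0.8, a = 0.5,
        phenols = 1.2, flavonoids = 0.8)
  if ("chestnut" %in% types)
    set("chestnut", ec = 1.0, ph = 0.5, pfund = 1.0, L = -1.0, a = 0.8,
        phenols = 0.8, flavonoids = 0.5)
  if ("eucalyptus" %in% types)
    set("eucalyptus", ec = -1.0, pfund = -1.0, L = 1.0, a = -0.8, b = 0.5,
        phenols = -0.8, flavonoids = -0.5)
  if ("blackberry" %in% types)
    set("blackberry", ec = -0.8, pfund = -0.5, L = 0.6, diastase = 0.5,
        phenols = -0.5)
  if ("honeydew" %in% types)
    set("honeydew", ec = 1.3, ph = 0.7, pfund = 0.7, L = -0.7, a = 0.3,
        phenols = 0.6, flavonoids = 0.3)
  if ("multifloral" %in% types)
    set("multifloral", ec = -0.4, pfund = -0.2, L = 0.3, phenols = -0.3)
  m
}

# Gaussian absorption bands per constituent: center (nm), width (nm),
# amplitude (absorbance per unit of the parameter). Amplitudes are sized so
# one global SD of a constituent moves the spectrum by ~0.05-0.06 AU at the
# band center; moisture gets the two water bands.
default_band_library <- function(parameters) {
  lib <- list(
    moisture   = rbind(c(1450, 40, 0.050), c(1190, 30, 0.025)),
    ec         = rbind(c(1630, 35, 2.0e-4)),
    ph         = rbind(c(1000, 25, 0.20)),
    hmf        = rbind(c(1530, 25, 0.30)),
    diastase   = rbind(c(1100, 30, 0.006)),
    pfund      = rbind(c(950, 40, 0.002)),
    L          = rbind(c(1250, 30, 0.005)),
    a          = rbind(c(1350, 25, 0.010)),
    b          = rbind(c(1580, 30, 0.006)),
    phenols    = rbind(c(1050, 28, 1.2e-3)),
    flavonoids = rbind(c(1410, 22, 0.018))
  )
  lib <- lapply(lib, function(b) {
    colnames(b) <- c("center", "width", "amplitude")
    b
  })
  lib[intersect(parameters, names(lib))]
}

# Per-type mean pollen percentages over ten taxa (summing to 100), centered
# on the published per-type compositions; rare or unresolved taxa are pooled
# into "Other".
default_pollen_means <- function() {
  taxa <- c("Castanea", "Eucalyptus", "Erica", "Rubus", "Cytisus",
            "Trifolium", "Echium", "Plantago", "Salix", "Other")
  mk <- function(...) {
    v <- stats::setNames(rep(0, length(taxa)), taxa)
    x <- c(...)
    v[names(x)] <- x
    stopifnot(abs(sum(v) - 100) < 1e-9)
    v
  }
  list(
    blackberry = mk(Rubus = 58.5, Castanea = 26.4, Erica = 3, Cytisus = 4,
                    Eucalyptus = 3, Echium = 2, Trifolium = 2, Plantago = 0.3,
                    Salix = 0.3, Other = 0.5),
    chestnut = mk(Castanea = 76.1, Rubus = 14.2, Cytisus = 3, Erica = 2.5,
                  Trifolium = 2, Echium = 1.5, Plantago = 0.2, Salix = 0.2,
                  Other = 0.3),
    eucalyptus = mk(Eucalyptus = 72.8, Cytisus = 6, Castanea = 8, Erica = 4,
                    Rubus = 4, Salix = 2, Other = 3.2),
    heather = mk(Castanea = 37.9, Erica = 35.5, Cytisus = 8, Eucalyptus = 6,
                 Rubus = 6, Echium = 3, Plantago = 2, Other = 1.6),
    honeydew = mk(Castanea = 52.3, Rubus = 18.6, Cytisus = 9, Plantago = 6,
                  Salix = 5, Erica = 5, Other = 4.1),
    multifloral = mk(Castanea = 41.3, Eucalyptus = 21.0, Rubus = 9, Cytisus = 8,
                     Erica = 7, Trifolium = 5, Salix = 3, Echium = 3,
                     Other = 2.7)
  )
}

# truncated normal by clip-and-resample (falls back to clamping after 200
# rounds, only reachable with pathological ranges)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:200) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate pollen profiles for labelled samples
#'
#' Each sample draws a composition from the Dirichlet distribution of its
#' honey type: mean percentages are the configured per-type means and the
#' configured precision controls sample-to-sample spread. Rows are expressed
#' in percent and sum to 100.
#'
#' @param config a `synthetic_config`.
#' @param labels character/factor vector of honey types.
#' @return data frame `sample_id` + one column per pollen taxon.
#' @export
generate_pollen_profiles <- function(config, labels) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(config$pollen_dirichlet))
  if (length(unknown) > 0)
    stop("unknown honey type(s): ", paste(unknown, collapse = ", "))
  taxa <- names(config$pollen_dirichlet[[1]])
  out <- matrix(0, length(labels), length(taxa),
                dimnames = list(NULL, taxa))
  for (i in seq_along(labels)) {
    alpha <- config$pollen_dirichlet[[labels[i]]] / 100 * config$pollen_precision
    alpha <- pmax(alpha, 1e-6)
    out[i, ] <- rdirichlet_one(alpha) * 100
  }
  data.frame(sample_id = names(labels) %||% paste0("S", seq_along(labels)),
             out, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gaussian_bands <- function(wl, bands) {
  # sum of Gaussian band profiles evaluated on the axis, unit concentration
  k <- numeric(length(wl))
  for (i in seq_len(nrow(bands)))
    k <- k + bands[i, "amplitude"] *
      exp(-((wl - bands[i, "center"])^2) / (2 * bands[i, "width"]^2))
  k
}

#' Generate a complete synthetic honey dataset
#'
#' Deterministic for a fixed config (the config carries the seed). Per
#' sample: the honey type fixes the constituent means; constituent values
#' are truncated-normal draws; the clean spectrum is the linear mixture of
#' the per-constituent band profiles weighted by the constituent values;
#' each of `replicate_scans` scans distorts it with a multiplicative scatter
#' factor, an additive + quadratic baseline and channel noise; the stored
#' spectrum is the replicate mean. Pollen profiles are Dirichlet draws and
#' the calibration/validation split is stratified by honey type.
#'
#' @param config a `synthetic_config`.
#' @return object of class `synthetic_dataset`: list with `spectra`
#'   (a `spectra_set`, absorbance), `reference` (data frame `sample_id` +
#'   11 parameters), `pollen` (data frame), `labels` (named character
#'   vector), `split` (named factor `calibration`/`validation`) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("H%03d", seq_len(n))
  labels <- rep(names(config$honey_type_counts), config$honey_type_counts)
  names(labels) <- ids

  cons <- config$constituents
  pars <- cons$parameter
  ref <- matrix(NA_real_, n, length(pars), dimnames = list(ids, pars))
  for (j in seq_along(pars)) {
    mu <- cons$mean[j] + config$type_offsets[labels, pars[j]] * cons$sd[j]
    sdw <- cons$sd[j] * config$within_sd_scale
    ref[, j] <- rtruncnorm(n, mu, sdw, cons$min[j], cons$max[j])
  }

  wl <- config$wavelengths
  K <- vapply(pars, function(p) {
    b <- config$band_library[[p]]
    if (is.null(b)) numeric(length(wl)) else gaussian_bands(wl, b)
  }, numeric(length(wl)))
  clean <- ref %*% t(K)                       # samples x channels
  u <- (wl - mean(range(wl))) / (diff(range(wl)) / 2)

  spec <- matrix(0, n, length(wl))
  for (r in seq_len(config$replicate_scans)) {
    mfac <- stats::rnorm(n, 0, config$scatter_sd)
    offs <- stats::rnorm(n, 0, config$offset_sd)
    quad <- stats::rnorm(n, 0, config$baseline_sd)
    eps <- matrix(stats::rnorm(n * length(wl), 0, config$noise_sd), n)
    spec <- spec + clean * (1 + mfac) + offs + outer(quad, u^2) + eps
  }
  spec <- spec / config$replicate_scans

  pollen <- generate_pollen_profiles(config, labels)
  pollen$sample_id <- ids

  ds <- structure(list(
    spectra = spectra_set(spec, wl, ids, "absorbance"),
    reference = data.frame(sample_id = ids, ref, check.names = FALSE,
                           row.names = NULL),
    pollen = pollen,
    labels = labels,
    split = NULL,
    config = config
  ), class = "synthetic_dataset")
  split_calibration_validation(ds, config$calibration_fraction,
                               seed = config$seed + 1L)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(x$labels), " samples, ",
      length(x$spectra$wavelengths), " channels",
      if (!is.null(x$split))
        paste0(" (", sum(x$split == "calibration"), " calibration / ",
               sum(x$split == "validation"), " validation)"),
      "\n", sep = "")
  invisible(x)
}

#' Assign a stratified calibration/validation split
#'
#' Sizes are the rounded per-type shares of `fraction`, adjusted so the
#' totals sum to n; the split is stratified by honey type so that every
#' type is represented in calibration whenever its count allows.
#'
#' @param dataset a `synthetic_dataset`.
#' @param fraction calibration fraction in (0, 1).
#' @param seed integer seed for the within-type draws.
#' @return the dataset with `split` filled (named factor).
#' @export
split_calibration_validation <- function(dataset, fraction = 0.84, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  labels <- dataset$labels
  ids <- names(labels)
  n <- length(ids)
  target_cal <- round(n * fraction)
  types <- unique(labels)
  per_type <- vapply(types, function(t) sum(labels == t), integer(1))
  cal_per_type <- round(per_type * fraction)
  # adjust rounding drift toward the exact total, preferring large types
  drift <- target_cal - sum(cal_per_type)
  ord <- order(-per_type)
  i <- 1
  while (drift != 0) {
    t <- ord[(i - 1) %% length(types) + 1]
    step <- sign(drift)
    cand <- cal_per_type[t] + step
    if (cand >= 0 && cand <= per_type[t]) {
      cal_per_type[t] <- cand
      drift <- drift - step
    }
    i <- i + 1
  }
  split <- stats::setNames(rep("validation", n), ids)
  for (t in types) {
    in_t <- ids[labels == t]
    take <- sample(in_t, cal_per_type[t])
    split[take] <- "calibration"
  }
  dataset$split <- factor(split, levels = c("calibration", "validation"))
  names(dataset$split) <- ids
  dataset
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `spectra.csv` (wide, wavelengths as columns), `reference.csv`,
#' `pollen.csv` and `labels.csv` (sample_id, honey_type, split) under `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(dataset$spectra, file.path(dir, "spectra.csv"))
  utils::write.csv(dataset$reference, file.path(dir, "reference.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$pollen, file.path(dir, "pollen.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = names(dataset$labels),
               honey_type = unname(dataset$labels),
               split = as.character(dataset$split[names(dataset$labels)])),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
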