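#' Run the full calibration study
#'
#' For every physicochemical parameter in the reference table: run the
#' treatment grid through the complete pipeline (preprocess, H > threshold
#' spectral screening, grouped cross-validation, T-criterion elimination,
#' refit), keep the winning treatment by highest RSQ / lowest SECV, and
#' externally validate the winner on the held-out validation samples. The
#' returned tables mirror the shape of published calibration and validation
#' descriptor tables.
#'
#' @param spectra a `spectra_set` of all samples (absorbance).
#' @param reference data frame with `sample_id` and one numeric column per
#'   parameter.
#' @param split named factor/character over sample ids with values
#'   `calibration` / `validation`.
#' @param parameters which reference columns to calibrate (default all but
#'   `sample_id`).
#' @param treatments treatment-string grid (default
#'   [default_treatment_grid()]).
#' @param h_threshold,t_threshold outlier thresholds (defaults 3 and 2.5).
#' @param n_groups cross-validation folds (default 8).
#' @param max_factors largest factor count tried (default 16).
#' @param seed seed governing fold assignment.
#' @param verbose print per-parameter progress and removed-sample logs.
#' @param ... further arguments to [calibrate_parameter()].
#' @return object of class `calibration_study`: list with
#'   `calibration_table` (one row per parameter: Variable, Math Treatment,
#'   N, Mean, SD, Est.Min, Est.Max, SEC, RSQ, SECV, RPD),
#'   `validation_table` (Variable, Mean Residual, RMSE, p), `models` (per
#'   parameter `calibration_result`), `removed` (per parameter: H and T
#'   outlier ids) and `grids` (per parameter full grid report).
#' @export
run_calibration_study <- function(spectra, reference, split,
                                  parameters = NULL,
                                  treatments = default_treatment_grid(),
                                  h_threshold = 3, t_threshold = 2.5,
                                  n_groups = 8, max_factors = 16,
                                  seed = 1L, verbose = FALSE, ...) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.null(parameters))
    parameters <- setdiff(names(reference), "sample_id")
  missing <- setdiff(parameters, names(reference))
  if (length(missing) > 0)
    stop("missing parameter column(s) in reference table: ",
         paste(missing, collapse = ", "),
         " (available: ", paste(setdiff(names(reference), "sample_id"),
                                collapse = ", "), ")")
  ids <- reference$sample_id
  split <- split[spectra$sample_ids]
  cal_ids <- spectra$sample_ids[split == "calibration"]
  val_ids <- spectra$sample_ids[split == "validation"]
  cal_spectra <- spectra[cal_ids]
  val_spectra <- spectra[val_ids]

  models <- list(); cal_rows <- list(); val_rows <- list()
  removed <- list(); grids <- list()
  for (par in parameters) {
    yall <- stats::setNames(reference[[par]], ids)
    if (verbose) message("calibrating ", par, " ...")
    sel <- select_best_model(cal_spectra, yall[cal_ids],
                             treatments = treatments,
                             h_threshold = h_threshold,
                             t_threshold = t_threshold,
                             n_groups = n_groups, max_factors = max_factors,
                             seed = seed, ...)
    best <- sel$best
    models[[par]] <- best
    grids[[par]] <- sel$report
    removed[[par]] <- list(H = best$h_outliers, T = best$t_outliers)
    if (verbose) {
      for (id in best$h_outliers) message("  removed ", id, " (H criterion)")
      for (id in best$t_outliers) message("  removed ", id, " (T criterion)")
      message("  ", par, ": removed ",
              length(best$h_outliers) + length(best$t_outliers), " samples")
    }
    s <- best$stats
    cal_rows[[par]] <- data.frame(
      Variable = par, `Math Treatment` = format(best$treatment),
      N = s$N, Mean = s$mean, SD = s$SD, Est.Min = s$est_min,
      Est.Max = s$est_max, SEC = s$SEC, RSQ = s$RSQ, SECV = s$SECV,
      RPD = s$RPD, check.names = FALSE)
    pred <- predict(best, val_spectra)
    v <- external_validate(yall[val_ids], pred)
    val_rows[[par]] <- data.frame(
      Variable = par, `Mean Residual` = v$mean_abs_residual, RMSE = v$RMSE,
      p = v$t_p_value, check.names = FALSE)
  }
  structure(list(
    calibration_table = do.call(rbind, c(cal_rows, make.row.names = FALSE)),
    validation_table = do.call(rbind, c(val_rows, make.row.names = FALSE)),
    models = models, removed = removed, grids = grids
  ), class = "calibration_study")
}

#' @export
print.calibration_study <- function(x, ...) {
  cat("<calibration_study> ", nrow(x$calibration_table), " parameters\n", sep = "")
  tbl <- x$calibration_table
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], function(v) round(v, 2))
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' Run the discriminant study
#'
#' Assembles the feature table (physicochemical parameters plus the main
#' pollen percentages), fits the LDA, and reports per-function diagnostics
#' and the confusion matrix (resubstitution by default; leave-one-out
#' optionally).
#'
#' @param reference data frame `sample_id` + physicochemical parameters.
#' @param pollen data frame `sample_id` + pollen-type percentages.
#' @param labels named honey-type vector over the sample ids.
#' @param pollen_vars which pollen taxa enter the model (default the four
#'   main types: Castanea, Eucalyptus, Erica, Rubus).
#' @param priors `"proportional"` or `"equal"`.
#' @param loo also compute a leave-one-out confusion matrix.
#' @param ridge ridge passed to [fit_lda()].
#' @return object of class `discriminant_study`: list with `model`
#'   (`lda_model`), `diagnostics` (Table-5-shaped data frame), `confusion`
#'   (`confusion_report`, resubstitution), `loo_confusion` (or `NULL`),
#'   `features` (the assembled data frame) and `scores` (canonical scores).
#' @export
run_discriminant_study <- function(reference, pollen, labels,
                                   pollen_vars = c("Castanea", "Eucalyptus",
                                                   "Erica", "Rubus"),
                                   priors = "proportional", loo = FALSE,
                                   ridge = 0) {
  ids <- reference$sample_id
  miss <- setdiff(pollen_vars, names(pollen))
  if (length(miss) > 0)
    stop("pollen table lacks variable(s): ", paste(miss, collapse = ", "))
  po <- pollen[match(ids, pollen$sample_id), pollen_vars, drop = FALSE]
  feats <- cbind(reference[setdiff(names(reference), "sample_id")], po)
  rownames(feats) <- ids
  lab <- labels[ids]
  counts <- table(lab)
  if (any(counts < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))

  model <- fit_lda(feats, lab, priors = priors, ridge = ridge)
  diag <- function_diagnostics(model)
  cls <- classify(model, feats)
  conf <- confusion_report(lab, cls$labels)

  loo_conf <- NULL
  if (loo) {
    pred <- character(length(ids))
    for (i in seq_along(ids)) {
      m <- fit_lda(feats[-i, , drop = FALSE], lab[-i], priors = priors,
                   ridge = ridge)
      pred[i] <- as.character(classify(m, feats[i, , drop = FALSE])$labels)
    }
    loo_conf <- confusion_report(lab, factor(pred, levels = levels(factor(lab))))
  }
  structure(list(model = model, diagnostics = diag, confusion = conf,
                 loo_confusion = loo_conf, features = feats,
                 scores = cls$scores),
            class = "discriminant_study")
}

#' @export
print.discriminant_study <- function(x, ...) {
  cat("<discriminant_study>\n")
  d <- x$diagnostics
  d[] <- lapply(d, function(v) if (is.numeric(v)) round(v, 2) else v)
  print(d, row.names = FALSE)
  print(x$confusion)
  invisible(x)
}

write_study_csvs <- function(study, dir, what = c("calibration", "lda")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if ("calibration" %in% what && inherits(study, "calibration_study")) {
    utils::write.csv(round_display(study$calibration_table),
                     file.path(dir, "calibration_table.csv"), row.names = FALSE)
    utils::write.csv(round_display(study$validation_table),
                     file.path(dir, "validation_table.csv"), row.names = FALSE)
    utils::write.csv(study$calibration_table,
                     file.path(dir, "calibration_table_full.csv"),
                     row.names = FALSE)
    utils::write.csv(study$validation_table,
                     file.path(dir, "validation_table_full.csv"),
                     row.names = FALSE)
  }
  if ("lda" %in% what && inherits(study, "discriminant_study")) {
    utils::write.csv(round_display(study$diagnostics),
                     file.path(dir, "lda_diagnostics.csv"), row.names = FALSE)
    cm <- as.data.frame(study$confusion$matrix)
    utils::write.csv(cbind(honey_type = rownames(study$confusion$matrix),
                           study$confusion$matrix),
                     file.path(dir, "lda_confusion.csv"), row.names = FALSE)
  }
  invisible(dir)
}

round_display <- function(df, digits = 2) {
  df[] <- lapply(df, function(v) if (is.numeric(v)) round(v, digits) else v)
  df
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `calibrate` (run the
#' calibration study), `lda` (run the discriminant study), `pollen-type`
#' (rule-based typing of a pollen CSV) and `all`. Inputs are the CSV layouts
#' written by `simulate`; one seed drives all randomness.
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
honeynir_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: honeynir <simulate|calibrate|lda|pollen-type|all> [options]\n",
        "common options: --data DIR --out DIR --seed INT\n",
        "calibrate: --treatments 'None 1,4,4,1;SNV 1,4,4,1' --cv-groups INT",
        " --h-threshold X --t-threshold X\n",
        "lda: --priors proportional|equal --loo\n", sep = "")
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- list(
    optparse::make_option("--data", type = "character", default = "."),
    optparse::make_option("--out", type = "character", default = "honeynir_out"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-samples", type = "integer", default = 100L,
                          dest = "n_samples"),
    optparse::make_option("--treatments", type = "character", default = NULL),
    optparse::make_option("--cv-groups", type = "integer", default = 8L,
                          dest = "cv_groups"),
    optparse::make_option("--h-threshold", type = "double", default = 3,
                          dest = "h_threshold"),
    optparse::make_option("--t-threshold", type = "double", default = 2.5,
                          dest = "t_threshold"),
    optparse::make_option("--max-factors", type = "integer", default = 16L,
                          dest = "max_factors"),
    optparse::make_option("--priors", type = "character", default = "proportional"),
    optparse::make_option("--loo", action = "store_true", default = FALSE)
  )
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = args[-1])

  read_inputs <- function(dir) {
    list(
      spectra = read_spectra_csv(file.path(dir, "spectra.csv")),
      reference = utils::read.csv(file.path(dir, "reference.csv"),
                                  check.names = FALSE),
      pollen = utils::read.csv(file.path(dir, "pollen.csv"),
                               check.names = FALSE),
      labels = {
        l <- utils::read.csv(file.path(dir, "labels.csv"))
        stats::setNames(as.character(l$honey_type), l$sample_id)
      },
      split = {
        l <- utils::read.csv(file.path(dir, "labels.csv"))
        stats::setNames(factor(l$split, c("calibration", "validation")),
                        l$sample_id)
      }
    )
  }

  if (cmd == "simulate") {
    cfg <- synthetic_config(n_samples = parsed$n_samples, seed = parsed$seed)
    ds <- generate_dataset(cfg)
    write_dataset_csv(ds, parsed$out)
    cat("wrote synthetic dataset (", length(ds$labels), " samples) to ",
        parsed$out, "\n", sep = "")
    return(invisible(0L))
  }

  treatments <- if (is.null(parsed$treatments)) default_treatment_grid()
                else trimws(strsplit(parsed$treatments, ";")[[1]])

  if (cmd %in% c("calibrate", "all")) {
    inp <- read_inputs(parsed$data)
    study <- run_calibration_study(
      inp$spectra, inp$reference, inp$split, treatments = treatments,
      h_threshold = parsed$h_threshold, t_threshold = parsed$t_threshold,
      n_groups = parsed$cv_groups, max_factors = parsed$max_factors,
      seed = parsed$seed, verbose = TRUE)
    write_study_csvs(study, parsed$out, "calibration")
    print(study)
  }
  if (cmd %in% c("lda", "all")) {
    inp <- read_inputs(parsed$data)
    study <- run_discriminant_study(inp$reference, inp$pollen, inp$labels,
                                    priors = parsed$priors, loo = parsed$loo)
    write_study_csvs(study, parsed$out, "lda")
    print(study)
  }
  if (cmd == "pollen-type") {
    inp <- read_inputs(parsed$data)
    ec <- if ("ec" %in% names(inp$reference)) inp$reference$ec / 1000 else NULL
    types <- assign_honey_types(inp$pollen, ec_ms_cm = ec)
    dir.create(parsed$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(types, file.path(parsed$out, "honey_types.csv"),
                     row.names = FALSE)
    cat("typed ", nrow(types), " samples -> ",
        file.path(parsed$out, "honey_types.csv"), "\n", sep = "")
  }
  if (!cmd %in% c("simulate", "calibrate", "lda", "pollen-type", "all"))
    stop("unknown subcommand '", cmd, "'")
  invisible(0L)
}
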