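#' Grouped cross-validation of an MPLS calibration
#'
#' Samples are partitioned at random into `n_groups` folds; each fold is
#' predicted by a model developed on the remaining folds, so every sample is
#' predicted exactly once per factor count. The per-factor standard error of
#' cross-validation SECV (root mean squared CV residual, denominator N)
#' is the single best estimate of prediction capability and drives the
#' choice of factor count.
#'
#' @param X numeric matrix, samples x channels.
#' @param y numeric response vector.
#' @param max_factors largest factor count to evaluate.
#' @param n_groups number of folds (default 8).
#' @param seed integer seed for the fold assignment.
#' @param modified use MPLS residual scaling (default `TRUE`).
#' @return object of class `mpls_cv` with `secv` (per-factor SECV = RMSECV),
#'   `predictions` (samples x factors CV prediction matrix), `folds`
#'   (fold id per sample), `best_factors` (argmin SECV) and
#'   `parsimonious_factors` (smallest factor count with SECV within 2
#'   percent of the minimum).
#' @export
cross_validate <- function(X, y, max_factors = 16, n_groups = 8,
                           seed = NULL, modified = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_groups < 2 || n_groups > n)
    stop("n_groups must be between 2 and the sample count")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep_len(seq_len(n_groups), n))
  sizes <- tabulate(folds, n_groups)
  if (any(sizes < 1)) stop("cross-validation fold with no samples")
  amax <- min(max_factors, n - max(sizes) - 1L, ncol(X))
  if (amax < 1) stop("too few samples for even one factor per fold")

  pred <- matrix(NA_real_, n, amax)
  for (gidx in seq_len(n_groups)) {
    hold <- folds == gidx
    fit <- fit_mpls(X[!hold, , drop = FALSE], y[!hold], amax, modified = modified)
    for (a in seq_len(fit$n_factors))
      pred[hold, a] <- predict(fit, X[hold, , drop = FALSE], n_factors = a)
    if (fit$n_factors < amax)  # degenerate fold: reuse deepest available factor
      for (a in (fit$n_factors + 1):amax)
        pred[hold, a] <- pred[hold, fit$n_factors]
  }
  secv <- sqrt(colMeans((pred - y)^2))
  best <- which.min(secv)
  pars <- which(secv <= min(secv) * 1.02)[1]
  structure(list(secv = secv, rmsecv = secv, predictions = pred,
                 folds = folds, best_factors = best,
                 parsimonious_factors = pars),
            class = "mpls_cv")
}

#' @export
print.mpls_cv <- function(x, ...) {
  cat("<mpls_cv> ", length(x$secv), " factor counts, min SECV ",
      format(min(x$secv), digits = 4), " at ", x$best_factors, " factors\n",
      sep = "")
  invisible(x)
}

#' Chemical outlier elimination by the T criterion
#'
#' After a calibration fit, the standardized residual T_i = |e_i| / SEC is
#' computed; samples with T at or above the threshold (conventionally 2.5)
#' are chemical outliers — their reference value is inconsistent with their
#' spectrum — and are removed, the model refitted, and the screen repeated
#' up to `max_passes` times or until nothing is removed.
#'
#' @param X numeric matrix, samples x channels.
#' @param y numeric response vector.
#' @param n_factors factor count for each refit.
#' @param threshold T threshold (default 2.5); `Inf` disables elimination.
#' @param max_passes maximum elimination passes (default 2).
#' @param modified use MPLS residual scaling.
#' @return list with `model` (final `mpls_model`), `retained` (logical over
#'   the input rows), `removed` (integer indices removed, in removal order)
#'   and `passes`.
#' @export
eliminate_t_outliers <- function(X, y, n_factors, threshold = 2.5,
                                 max_passes = 2, modified = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  keep <- rep(TRUE, nrow(X))
  removed <- integer(0)
  fit <- fit_mpls(X, y, n_factors, modified = modified)
  passes <- 0L
  while (passes < max_passes) {
    e <- fit$residuals
    k <- fit$n_factors
    nn <- sum(keep)
    if (nn <= k + 2) break
    sec <- sqrt(sum(e^2) / (nn - k - 1))
    if (sec == 0) break
    tvals <- abs(e) / sec
    bad <- which(tvals >= threshold)
    if (length(bad) == 0) break
    idx_keep <- which(keep)
    if (length(bad) >= nn) stop("T elimination would remove every sample")
    removed <- c(removed, idx_keep[bad])
    keep[idx_keep[bad]] <- FALSE
    passes <- passes + 1L
    fit <- fit_mpls(X[keep, , drop = FALSE], y[keep], n_factors,
                    modified = modified)
  }
  list(model = fit, retained = keep, removed = removed, passes = passes)
}

#' Calibration statistics (Table-2 style descriptors)
#'
#' Computes the standard chemometric calibration descriptors on the retained
#' samples: N, mean and SD of the reference values (n - 1 denominator), the
#' estimated range mean +/- 3 SD (floored at 0 for non-negative parameters),
#' SEC = sqrt(SSE / (N - n_factors - 1)), RSQ = 1 - SSE/SST on the
#' calibration fit, SECV = sqrt(SSE_cv / N), and RPD. RPD defaults to
#' SD / SEC (the arithmetic that reproduces published descriptor tables);
#' `rpd_denominator = "SECV"` gives the SD / SECV variant.
#'
#' @param y_ref reference values of the retained samples.
#' @param y_fit fitted (calibration) values, aligned with `y_ref`.
#' @param y_cv cross-validation predictions aligned with `y_ref`, or `NULL`
#'   (SECV reported as `NA`).
#' @param n_factors factor count used by the model.
#' @param non_negative floor the estimated range at 0 (default `TRUE`).
#' @param rpd_denominator `"SEC"` (default) or `"SECV"`.
#' @return object of class `calibration_stats`: a list with `N`, `mean`,
#'   `SD`, `est_min`, `est_max`, `SEC`, `RSQ`, `SECV`, `RMSECV`, `RPD`,
#'   `n_factors`.
#' @export
calibration_stats <- function(y_ref, y_fit, y_cv = NULL, n_factors,
                              non_negative = TRUE,
                              rpd_denominator = c("SEC", "SECV")) {
  rpd_denominator <- match.arg(rpd_denominator)
  y_ref <- as.numeric(y_ref); y_fit <- as.numeric(y_fit)
  n <- length(y_ref)
  if (length(y_fit) != n) stop("y_fit must align with y_ref")
  if (n <= n_factors + 1)
    stop("need N > n_factors + 1 (N = ", n, ", factors = ", n_factors, ")")
  e <- y_ref - y_fit
  sse <- sum(e^2)
  sst <- sum((y_ref - mean(y_ref))^2)
  sdv <- stats::sd(y_ref)
  sec <- sqrt(sse / (n - n_factors - 1))
  rsq <- if (sst == 0) NA_real_ else 1 - sse / sst
  secv <- if (is.null(y_cv)) NA_real_ else {
    if (length(y_cv) != n) stop("y_cv must align with y_ref")
    sqrt(sum((y_ref - y_cv)^2) / n)
  }
  den <- if (rpd_denominator == "SEC") sec else secv
  rpd <- if (is.na(den)) NA_real_ else if (den == 0) Inf else sdv / den
  est_min <- mean(y_ref) - 3 * sdv
  if (non_negative) est_min <- max(est_min, 0)
  structure(list(N = n, mean = mean(y_ref), SD = sdv,
                 est_min = est_min, est_max = mean(y_ref) + 3 * sdv,
                 SEC = sec, RSQ = rsq, SECV = secv, RMSECV = secv,
                 RPD = rpd, n_factors = n_factors),
            class = "calibration_stats")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf(
    "<calibration_stats> N=%d mean=%.2f SD=%.2f SEC=%.3f RSQ=%.3f SECV=%.3f RPD=%.2f (%d factors)\n",
    x$N, x$mean, x$SD, x$SEC, x$RSQ, x$SECV, x$RPD, x$n_factors))
  invisible(x)
}

#' External validation statistics (Table-3 style)
#'
#' Compares NIR predictions with reference values on an independent
#' validation set: mean absolute residual, RMSE, bias (mean signed
#' residual), SEP (sqrt(SSE/(n-1))), bias-corrected SEP(C)
#' (sqrt(sum((e - bias)^2)/(n-1))) and the two-sided paired Student test of
#' predicted versus reference. The method is accepted as comparable to the
#' reference assay when p > alpha.
#'
#' @param y_ref reference values.
#' @param y_pred NIR-predicted values, aligned.
#' @param alpha significance level for the comparability flag (default 0.05).
#' @return object of class `validation_stats`: list with
#'   `mean_abs_residual`, `RMSE`, `bias`, `SEP`, `SEP_C`, `t_statistic`,
#'   `t_p_value`, `comparable`, `n`.
#' @export
external_validate <- function(y_ref, y_pred, alpha = 0.05) {
  y_ref <- as.numeric(y_ref); y_pred <- as.numeric(y_pred)
  n <- length(y_ref)
  if (length(y_pred) != n) stop("y_pred must align with y_ref")
  if (n < 3) stop("external validation needs at least 3 pairs")
  e <- y_ref - y_pred
  bias <- mean(e)
  sep <- sqrt(sum(e^2) / (n - 1))
  sep_c <- sqrt(sum((e - bias)^2) / (n - 1))
  rmse <- sqrt(mean(e^2))
  if (sep_c == 0) {
    tstat <- if (bias == 0) 0 else Inf * sign(bias)
    pval <- if (bias == 0) 1 else 0
  } else {
    tstat <- bias / (sep_c / sqrt(n))
    pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  structure(list(mean_abs_residual = mean(abs(e)), RMSE = rmse, bias = bias,
                 SEP = sep, SEP_C = sep_c, t_statistic = tstat,
                 t_p_value = pval, comparable = pval > alpha, n = n),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf(
    "<validation_stats> n=%d mean|res|=%.3f RMSE=%.3f bias=%.3f SEP=%.3f SEP(C)=%.3f p=%.3f (%s)\n",
    x$n, x$mean_abs_residual, x$RMSE, x$bias, x$SEP, x$SEP_C, x$t_p_value,
    if (x$comparable) "comparable" else "different"))
  invisible(x)
}

#' Full calibration pipeline for one parameter and one treatment
#'
#' Runs the complete per-parameter workflow: apply the mathematical
#' treatment, screen spectral outliers with the Mahalanobis H > threshold
#' rule in PCA score space, choose the factor count by grouped
#' cross-validation (minimum SECV; optionally the smallest count within 2
#' percent), eliminate chemical outliers by the T criterion, refit, and
#' rerun cross-validation on the retained set so SECV describes the final
#' model.
#'
#' @param spectra a `spectra_set` of calibration samples (absorbance).
#' @param y named or aligned numeric vector of reference values.
#' @param treatment a `math_treatment` or treatment string.
#' @param h_threshold Mahalanobis H flagging threshold (default 3, `Inf`
#'   disables spectral screening).
#' @param t_threshold chemical outlier threshold (default 2.5, `Inf`
#'   disables).
#' @param max_factors largest factor count tried (default 16).
#' @param n_groups cross-validation folds (default 8).
#' @param seed fold-assignment seed.
#' @param pca_variance_pct retain enough PCA components to explain this
#'   cumulative percentage for H screening (default 99.5, capped at 10
#'   components).
#' @param parsimonious choose the smallest factor count within 2 percent of
#'   the minimum SECV instead of the argmin (default `TRUE`).
#' @param modified use MPLS residual scaling (default `TRUE`).
#' @param non_negative floor the estimated range at 0.
#' @param rpd_denominator `"SEC"` or `"SECV"`.
#' @return object of class `calibration_result`: list with `model`
#'   (`mpls_model`), `treatment`, `stats` (`calibration_stats`),
#'   `retained_ids`, `h_outliers`, `t_outliers`, `n_factors`, `cv`
#'   (`mpls_cv` on retained samples), `msc_reference` (when relevant) and
#'   `pca` (the screening model).
#' @export
calibrate_parameter <- function(spectra, y, treatment,
                                h_threshold = 3, t_threshold = 2.5,
                                max_factors = 16, n_groups = 8, seed = NULL,
                                pca_variance_pct = 99.5, parsimonious = TRUE,
                                modified = TRUE, non_negative = TRUE,
                                rpd_denominator = "SEC") {
  stopifnot(inherits(spectra, "spectra_set"))
  tr <- parse_treatment(treatment)
  if (!is.null(names(y))) y <- y[spectra$sample_ids]
  y <- as.numeric(y)
  if (length(y) != length(spectra$sample_ids))
    stop("y must have one value per spectrum")

  prep <- apply_treatment(spectra, tr)
  msc_ref <- attr(prep, "msc_reference")
  X <- prep$values
  ids <- prep$sample_ids

  # spectral screening: H > threshold in PCA score space
  h_out <- character(0)
  pca <- NULL
  if (is.finite(h_threshold)) {
    full <- fit_pca(X)
    k <- which(full$explained_variance_pct >= pca_variance_pct)[1]
    if (is.na(k)) k <- full$n_components
    k <- max(2L, min(k, 10L, full$n_components))
    pca <- fit_pca(X, k)
    h_out <- screen_h(pca, threshold = h_threshold)$outlier_ids
  }
  keep <- !(ids %in% h_out)
  if (sum(keep) < 10) stop("H screening left fewer than 10 samples")
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]

  cv0 <- cross_validate(Xk, yk, max_factors = max_factors,
                        n_groups = n_groups, seed = seed, modified = modified)
  a <- if (parsimonious) cv0$parsimonious_factors else cv0$best_factors

  el <- eliminate_t_outliers(Xk, yk, a, threshold = t_threshold,
                             modified = modified)
  ids_k <- ids[keep]
  t_out <- ids_k[!el$retained]
  retained_ids <- ids_k[el$retained]
  Xr <- Xk[el$retained, , drop = FALSE]
  yr <- yk[el$retained]

  cv1 <- cross_validate(Xr, yr, max_factors = max(a, 2L), n_groups = n_groups,
                        seed = seed, modified = modified)
  a_final <- min(a, ncol(cv1$predictions))
  stats <- calibration_stats(yr, el$model$fitted, cv1$predictions[, a_final],
                             n_factors = el$model$n_factors,
                             non_negative = non_negative,
                             rpd_denominator = rpd_denominator)
  structure(list(model = el$model, treatment = tr, stats = stats,
                 retained_ids = retained_ids, h_outliers = h_out,
                 t_outliers = t_out, n_factors = el$model$n_factors,
                 cv = cv1, msc_reference = msc_ref, pca = pca),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", format(x$treatment), ", ",
      x$n_factors, " factors, N=", x$stats$N,
      " (H outliers: ", length(x$h_outliers),
      ", T outliers: ", length(x$t_outliers), ")\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Predict a parameter for new spectra from a calibration result
#'
#' Re-applies the stored treatment (with the calibration MSC reference when
#' relevant) and the MPLS coefficients.
#'
#' @param object a `calibration_result`.
#' @param newdata a `spectra_set` on the same wavelength axis as training.
#' @param ... unused.
#' @return numeric predictions named by sample id.
#' @export
predict.calibration_result <- function(object, newdata, ...) {
  prep <- apply_treatment(newdata, object$treatment,
                          msc_reference = object$msc_reference)
  out <- predict(object$model, prep$values)
  names(out) <- prep$sample_ids
  out
}

#' Default mathematical-treatment grid
#'
#' The cross product of the five scatter corrections with five derivative
#' codes spanning none, first and second derivatives at increasing gap and
#' smoothing footprints.
#'
#' @return character vector of treatment strings.
#' @export
default_treatment_grid <- function() {
  scat <- c("None", "SNV", "MSC", "Detrend only", "SNV-DT")
  der <- c("0,0,1,1", "1,4,4,1", "2,4,4,1", "2,8,6,1", "2,10,10,1")
  as.vector(outer(scat, der, paste))
}

#' Select the best treatment for one parameter
#'
#' Runs [calibrate_parameter()] for every candidate treatment and keeps the
#' winner by the published rule: highest RSQ (ties broken at 4 decimal
#' places), then lowest SECV, then fewest factors. The full grid report is
#' returned for inspection.
#'
#' @param spectra calibration `spectra_set`.
#' @param y reference values aligned with the spectra.
#' @param treatments character vector of treatment strings (default
#'   [default_treatment_grid()]).
#' @param ... passed to [calibrate_parameter()].
#' @return list with `best` (a `calibration_result`), `report` (data frame,
#'   one row per candidate: Treatment, N, Factors, SEC, RSQ, SECV, RPD) and
#'   `results` (all `calibration_result`s, named by treatment).
#' @export
select_best_model <- function(spectra, y, treatments = default_treatment_grid(),
                              ...) {
  if (length(treatments) == 0) stop("empty treatment grid")
  results <- list()
  rows <- list()
  for (tstr in treatments) {
    res <- tryCatch(calibrate_parameter(spectra, y, tstr, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[tstr]] <- data.frame(Treatment = tstr, N = NA, Factors = NA,
                                 SEC = NA, RSQ = NA, SECV = NA, RPD = NA,
                                 Error = conditionMessage(res))
      next
    }
    results[[tstr]] <- res
    s <- res$stats
    rows[[tstr]] <- data.frame(Treatment = tstr, N = s$N, Factors = res$n_factors,
                               SEC = s$SEC, RSQ = s$RSQ, SECV = s$SECV,
                               RPD = s$RPD, Error = NA_character_)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (length(results) == 0)
    stop("treatment grid exhausted: every candidate failed")
  rsq4 <- vapply(results, function(r) round(r$stats$RSQ, 4), numeric(1))
  secv <- vapply(results, function(r) r$stats$SECV, numeric(1))
  nfac <- vapply(results, function(r) r$n_factors, numeric(1))
  ord <- order(-rsq4, secv, nfac)
  list(best = results[[ord[1]]], report = report, results = results)
}
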