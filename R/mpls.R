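#' Modified partial least squares (MPLS) regression
#'
#' PLS1 by NIPALS with the Shenk-Westerhaus modification: after each factor
#' is extracted, the X-residual columns and the y residual are divided by
#' their standard deviations before the next factor is computed, so later
#' factors weight all remaining wavelengths evenly. All scalings are
#' recorded and folded into the final coefficient vector, so prediction is
#' an exact linear map. With `modified = FALSE` the fit is textbook PLS1.
#'
#' @param X numeric matrix, samples x channels (already preprocessed).
#' @param y numeric response vector.
#' @param n_factors number of latent factors to extract.
#' @param modified apply the per-factor residual re-standardization
#'   (default `TRUE`).
#' @return object of class `mpls_model` with elements `n_factors` (factors
#'   actually extracted), `x_mean`, `y_mean`, `coefficients` (channels, for
#'   the full factor count), `coef_by_factor` (channels x factors,
#'   cumulative coefficients after 1..A factors), `fitted`, `residuals`.
#' @export
fit_mpls <- function(X, y, n_factors, modified = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (stats::sd(y) == 0) stop("zero-variance response y")
  n_factors <- min(n_factors, n - 1L, p)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  # linear map from centered input to the current residual space, and the
  # cumulative y-scale undoing the per-factor standardizations
  M <- diag(p)
  gamma <- 1
  B <- numeric(p)
  coef_by_factor <- matrix(0, p, n_factors)
  tiny <- 1e-12

  a <- 0L
  for (k in seq_len(n_factors)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < tiny) break
    w <- w / nw
    tt <- drop(Xc %*% w)
    ss <- sum(tt^2)
    if (ss < tiny) break
    pl <- drop(crossprod(Xc, tt)) / ss
    q <- sum(yc * tt) / ss

    B <- B + gamma * q * drop(crossprod(M, w))
    a <- k
    coef_by_factor[, k] <- B

    Xc <- Xc - tcrossprod(tt, pl)
    yc <- yc - q * tt
    M <- M - pl %*% crossprod(w, M)

    if (modified && k < n_factors) {
      sx <- apply(Xc, 2, stats::sd)
      sx[sx < tiny] <- 1
      Xc <- sweep(Xc, 2, sx, "/")
      M <- M / sx
      sy <- stats::sd(yc)
      if (sy < tiny) sy <- 1
      yc <- yc / sy
      gamma <- gamma * sy
    }
  }
  if (a == 0L) stop("no PLS factor could be extracted (X'y is zero)")
  coef_by_factor <- coef_by_factor[, seq_len(a), drop = FALSE]
  fitted <- drop(sweep(X, 2, x_mean) %*% coef_by_factor[, a]) + y_mean
  structure(list(
    n_factors = a, modified = modified,
    x_mean = x_mean, y_mean = y_mean,
    coefficients = coef_by_factor[, a],
    coef_by_factor = coef_by_factor,
    fitted = fitted, residuals = y - fitted
  ), class = "mpls_model")
}

#' @export
print.mpls_model <- function(x, ...) {
  cat("<mpls_model> ", x$n_factors, " factors (",
      if (x$modified) "modified" else "standard", " PLS1), ",
      length(x$coefficients), " channels\n", sep = "")
  invisible(x)
}

#' Predict from an MPLS model
#'
#' @param object an `mpls_model`.
#' @param newdata matrix or `spectra_set` with the channels the model was
#'   fitted on.
#' @param n_factors predict with a truncated factor count (default: all
#'   extracted factors).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mpls_model <- function(object, newdata, n_factors = object$n_factors, ...) {
  x <- if (inherits(newdata, "spectra_set")) newdata$values else as.matrix(newdata)
  if (ncol(x) != length(object$x_mean))
    stop("newdata channel count does not match the fitted model")
  if (n_factors < 1 || n_factors > object$n_factors)
    stop("n_factors must be in 1..", object$n_factors)
  b <- object$coef_by_factor[, n_factors]
  drop(sweep(x, 2, object$x_mean) %*% b) + object$y_mean
}
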