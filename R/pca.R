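#' Principal component analysis of a spectra set
#'
#' Column-centered PCA via singular value decomposition. Components are
#' ordered by decreasing explained variance; scores are the centered data
#' projected on the loadings.
#'
#' @param spectra a `spectra_set` (or plain matrix).
#' @param n_components number of components to retain; defaults to the full
#'   rank.
#' @return object of class `pca_model` with elements `loadings`
#'   (channels x components, orthonormal), `scores` (samples x components),
#'   `center`, `sdev` (component standard deviations, n - 1 denominator),
#'   `explained_variance_pct` (cumulative percent) and `n_components`.
#' @export
fit_pca <- function(spectra, n_components = NULL) {
  x <- if (inherits(spectra, "spectra_set")) spectra$values else as.matrix(spectra)
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 samples")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds rank (", rank, ")")
  k <- n_components
  var_all <- sv$d^2 / (n - 1)
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k, k)
  rownames(scores) <- rownames(x)
  structure(list(
    n_components = k,
    loadings = sv$v[, 1:k, drop = FALSE],
    scores = scores,
    center = center,
    sdev = sv$d[1:k] / sqrt(n - 1),
    explained_variance_pct = cumsum(var_all[1:k]) / sum(var_all) * 100
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", x$n_components, " components, cumulative variance ",
      sprintf("%.2f%%", x$explained_variance_pct[x$n_components]), "\n", sep = "")
  invisible(x)
}

#' Project new spectra on a fitted PCA
#'
#' @param object a `pca_model`.
#' @param newdata a `spectra_set` or matrix with the same channels.
#' @param ... unused.
#' @return samples x components score matrix.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "spectra_set")) newdata$values else as.matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("newdata channel count does not match the fitted PCA")
  sweep(x, 2, object$center) %*% object$loadings
}

#' Mahalanobis H-statistic spectral outlier screening
#'
#' In k-dimensional principal-component score space the squared Mahalanobis
#' distance of sample i reduces (because score dimensions are uncorrelated)
#' to sum_j score_ij^2 / var_j. The H-statistic divides this by k, so its
#' population mean is (n - 1)/n regardless of k; spectra with H above the
#' threshold (conventionally 3) do not belong to the calibration population
#' and are excluded before any equation is developed.
#'
#' @param pca a fitted `pca_model`.
#' @param threshold flagging threshold (default 3).
#' @param scores optional score matrix to screen (defaults to the training
#'   scores; supply `predict(pca, new_spectra)` to screen new samples).
#' @return object of class `h_screen` with `h_values` (named), `threshold`
#'   and `outlier_ids`.
#' @export
screen_h <- function(pca, threshold = 3, scores = NULL) {
  stopifnot(inherits(pca, "pca_model"))
  if (is.null(scores)) scores <- pca$scores
  k <- pca$n_components
  v <- pca$sdev^2
  if (any(v <= 0))
    stop("singular score covariance; refit the PCA with fewer components")
  h <- rowSums(sweep(scores^2, 2, v, "/")) / k
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_along(h))
  names(h) <- ids
  structure(list(h_values = h, threshold = threshold,
                 outlier_ids = ids[h > threshold]),
            class = "h_screen")
}

#' @export
print.h_screen <- function(x, ...) {
  cat("<h_screen> ", length(x$h_values), " samples, threshold ", x$threshold,
      ", ", length(x$outlier_ids), " flagged\n", sep = "")
  invisible(x)
}
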