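#' Linear discriminant analysis (canonical variates)
#'
#' Finds linear combinations of the predictors that maximize the ratio of
#' between-group to within-group scatter, by solving the generalized
#' eigenproblem B a = lambda W a where W is the pooled within-group SSCP
#' matrix and B the between-group SSCP matrix. Axes are scaled so canonical
#' scores have unit pooled within-group variance; at most min(g - 1, p)
#' functions carry discriminating power.
#'
#' @param features data frame or matrix, samples x predictors (numeric).
#' @param labels factor or character vector of group membership.
#' @param priors `"proportional"` (default, group sizes) or `"equal"`, or a
#'   named numeric vector summing to 1.
#' @param ridge if the within-group scatter is singular, add
#'   `ridge * trace(W)/p` to its diagonal and warn; `ridge = 0` raises an
#'   error instead (default `0`).
#' @return object of class `lda_model`: `variables`, `groups`, `counts`,
#'   `priors`, `eigenvalues` (descending), `axes` (p x m raw coefficient
#'   matrix), `center` (grand mean), `group_centroids` (g x m canonical
#'   means), `N`, `p`.
#' @export
fit_lda <- function(features, labels, priors = c("proportional", "equal"),
                    ridge = 0) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  labels <- factor(labels)
  groups <- levels(labels)
  g <- length(groups)
  n <- nrow(x); p <- ncol(x)
  if (g < 2) stop("need at least 2 groups")
  counts <- table(labels)
  if (any(counts < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(groups[counts < 2], collapse = ", "))
  if (is.character(priors)) {
    priors <- match.arg(priors)
    pr <- if (priors == "proportional") as.numeric(counts) / n
          else rep(1 / g, g)
  } else {
    if (is.null(names(priors))) stop("numeric priors must be named by group")
    pr <- as.numeric(priors[groups])
    pr <- pr / sum(pr)
  }
  names(pr) <- groups

  grand <- colMeans(x)
  means <- rowsum(x, labels) / as.numeric(counts)
  # pooled within-group and between-group SSCP
  xc <- x - means[as.integer(labels), , drop = FALSE]
  W <- crossprod(xc)
  md <- sweep(means, 2, grand)
  B <- crossprod(md * sqrt(as.numeric(counts)))

  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) {
    if (ridge <= 0) {
      # name the offending variables: those whose within-group residual is
      # (numerically) a linear combination of the others
      qrW <- qr(xc)
      dep <- colnames(x)[qrW$pivot[-seq_len(qrW$rank)]]
      stop("singular within-group scatter (collinear variables: ",
           paste(dep, collapse = ", "),
           "); set ridge > 0 for a regularized fit")
    }
    warning("singular within-group scatter; applying ridge ", ridge)
    W <- W + diag(ridge * sum(diag(W)) / p, p)
    ch <- chol(W)
  }
  # symmetric reduction: eigen of L^-1 B L^-T with W = L L' (L = R', W = R'R)
  Z <- backsolve(ch, B, transpose = TRUE)          # R'^-1 B
  Y <- backsolve(ch, t(Z), transpose = TRUE)       # R'^-1 B R^-1
  es <- eigen((Y + t(Y)) / 2, symmetric = TRUE)
  m <- min(g - 1, p)
  lambda <- pmax(es$values[seq_len(m)], 0)
  U <- es$vectors[, seq_len(m), drop = FALSE]
  A <- backsolve(ch, U)              # raw axes: A' W A = I
  A <- A * sqrt(n - g)               # canonical within-group variance = 1
  rownames(A) <- colnames(x)
  centroids <- sweep(means, 2, grand) %*% A
  rownames(centroids) <- groups
  structure(list(variables = colnames(x), groups = groups,
                 counts = as.integer(counts), priors = pr,
                 eigenvalues = lambda, axes = A, center = grand,
                 group_centroids = centroids, N = n, p = p),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> ", length(x$groups), " groups, ", x$p, " variables, ",
      length(x$eigenvalues), " discriminant functions\n", sep = "")
  cat("eigenvalues:", format(x$eigenvalues, digits = 3), "\n")
  invisible(x)
}

#' Canonical scores for new observations
#'
#' @param object an `lda_model`.
#' @param newdata data frame or matrix carrying all model variables.
#' @param ... unused.
#' @return samples x functions canonical score matrix.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(df))
  if (length(miss) > 0)
    stop("missing variable(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(df[, object$variables, drop = FALSE])
  sweep(x, 2, object$center) %*% object$axes
}

#' Per-function diagnostics (eigenvalue, Wilks' lambda, Bartlett chi-square)
#'
#' For each discriminant function k with eigenvalue lambda_k:
#' relative percentage lambda_k / sum(lambda) x 100; canonical correlation
#' sqrt(lambda_k / (1 + lambda_k)); Wilks' lambda for functions k..m,
#' Lambda_k = prod over i >= k of 1/(1 + lambda_i); Bartlett's chi-square
#' approximation -(N - 1 - (p + g)/2) ln(Lambda_k) on
#' (p - k + 1)(g - k) degrees of freedom.
#'
#' @param model an `lda_model`, or a bare numeric vector of eigenvalues
#'   (then `N`, `p`, `g` must be given).
#' @param N,p,g training size, predictor count, group count (taken from the
#'   model when one is supplied).
#' @return data frame with columns `function.` (index), `eigenvalue`,
#'   `relative_pct`, `canonical_correlation`, `wilks_lambda`, `chi_square`,
#'   `df`, `p_value`.
#' @export
function_diagnostics <- function(model, N = NULL, p = NULL, g = NULL) {
  if (inherits(model, "lda_model")) {
    lambda <- model$eigenvalues
    N <- model$N; p <- model$p; g <- length(model$groups)
  } else {
    lambda <- as.numeric(model)
    if (is.null(N) || is.null(p) || is.null(g))
      stop("N, p and g are required when passing raw eigenvalues")
  }
  m <- length(lambda)
  k <- seq_len(m)
  # Wilks chain from the tail: Lambda_k = Lambda_{k+1} / (1 + lambda_k)
  wl <- rev(cumprod(rev(1 / (1 + lambda))))
  chi <- -(N - 1 - (p + g) / 2) * log(wl)
  df <- (p - k + 1) * (g - k)
  data.frame(
    function. = k,
    eigenvalue = lambda,
    relative_pct = lambda / sum(lambda) * 100,
    canonical_correlation = sqrt(lambda / (1 + lambda)),
    wilks_lambda = wl,
    chi_square = chi,
    df = df,
    p_value = stats::pchisq(chi, df, lower.tail = FALSE)
  )
}

#' Classify observations with a fitted LDA model
#'
#' Each observation is assigned to the group whose canonical centroid is
#' nearest in squared Euclidean distance, penalized by -2 ln(prior); ties
#' break deterministically by group order.
#'
#' @param model an `lda_model`.
#' @param features data frame or matrix carrying all model variables.
#' @return list with `labels` (factor of predictions) and `scores`
#'   (canonical score matrix).
#' @export
classify <- function(model, features) {
  sc <- predict(model, features)
  cent <- model$group_centroids
  d2 <- outer(rowSums(sc^2), rowSums(cent^2), "+") - 2 * sc %*% t(cent)
  d2 <- sweep(d2, 2, 2 * log(model$priors), "-")
  idx <- apply(d2, 1, which.min)
  list(labels = factor(model$groups[idx], levels = model$groups), scores = sc)
}

#' Confusion matrix report
#'
#' @param true_labels,predicted aligned label vectors over the same class
#'   set.
#' @return object of class `confusion_report`: `matrix` (g x g counts, rows
#'   true), `row_pcts`, `per_class_correct_pct`, `overall_correct_pct`, `N`.
#' @export
confusion_report <- function(true_labels, predicted) {
  true_labels <- factor(true_labels)
  lev <- levels(true_labels)
  predicted <- factor(predicted, levels = union(lev, levels(factor(predicted))))
  extra <- setdiff(levels(predicted), lev)
  if (length(extra) > 0 && any(table(predicted)[extra] > 0))
    stop("predicted labels outside the true class set: ",
         paste(extra, collapse = ", "))
  predicted <- factor(as.character(predicted), levels = lev)
  if (length(predicted) != length(true_labels))
    stop("label vectors must align")
  m <- table(true = true_labels, predicted = predicted)
  rs <- rowSums(m)
  row_pcts <- sweep(m, 1, pmax(rs, 1), "/") * 100
  per_class <- diag(row_pcts)
  overall <- 100 * sum(diag(m)) / sum(m)
  structure(list(matrix = unclass(m), row_pcts = unclass(row_pcts),
                 per_class_correct_pct = per_class,
                 overall_correct_pct = overall, N = sum(m)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("Percent of cases correctly classified: %.1f%%\n",
              x$overall_correct_pct))
  invisible(x)
}
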