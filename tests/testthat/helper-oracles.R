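# Independent oracles and tiny fixtures used across the suite.

# Small random spectra fixture on a short wavelength axis.
make_spectra <- function(n = 6, p = 20, seed = 1, representation = "absorbance") {
  set.seed(seed)
  wl <- seq(1000, 1000 + 6 * (p - 1), by = 6)
  base <- 0.5 + 0.3 * sin(seq(0, pi, length.out = p))
  vals <- t(replicate(n, base + rnorm(p, 0, 0.05)))
  if (representation == "reflectance") vals <- 10^(-abs(vals))
  spectra_set(vals, wl, representation = representation)
}

# Oracle PLS1 via the Krylov-subspace characterization: the a-factor PLS1
# coefficient vector is the least-squares solution restricted to
# span{s, As, ..., A^(a-1) s} with A = X'X and s = X'y (centered data).
# Entirely independent of the NIPALS recursion used by the package.
oracle_pls1 <- function(X, y, a) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  A <- crossprod(Xc)
  s <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(X), a)
  v <- s
  for (i in seq_len(a)) {
    K[, i] <- v
    v <- drop(A %*% v)
  }
  Q <- qr.Q(qr(K))
  M <- crossprod(Q, A %*% Q)
  b <- Q %*% solve(M, crossprod(Q, s))
  list(coefficients = drop(b), intercept = ym - sum(xm * b))
}

# Closed-form paired Student t-test.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * pt(-abs(t), n - 1))
}

# Reference table of honey types used by several tests.
honey_type_counts <- c(heather = 5, chestnut = 22, eucalyptus = 9,
                       blackberry = 10, honeydew = 18, multifloral = 36)

# Printed discriminant eigenvalues used for diagnostics arithmetic.
printed_eigenvalues <- c(3.64, 2.56, 1.73, 0.98, 0.48)

# Printed confusion-matrix counts (rows = true class).
printed_confusion <- function() {
  lev <- c("heather", "chestnut", "eucalyptus", "blackberry", "honeydew",
           "multifloral")
  m <- rbind(
    heather     = c(5, 0, 0, 0, 0, 0),
    chestnut    = c(0, 19, 0, 0, 3, 0),
    eucalyptus  = c(0, 0, 9, 0, 0, 0),
    blackberry  = c(0, 0, 0, 10, 0, 0),
    honeydew    = c(0, 2, 0, 0, 15, 1),
    multifloral = c(2, 1, 1, 1, 1, 30)
  )
  colnames(m) <- lev
  m
}

# Expand a count matrix into aligned true/predicted label vectors.
labels_from_counts <- function(m) {
  lev <- rownames(m)
  true <- character(0); pred <- character(0)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    k <- m[i, j]
    if (k > 0) {
      true <- c(true, rep(lev[i], k))
      pred <- c(pred, rep(lev[j], k))
    }
  }
  list(true = factor(true, lev), pred = factor(pred, lev))
}

# Construct reference/fitted vectors with an exact SD and exact SEC, to
# exercise the descriptor arithmetic at chosen values.
make_sd_sec_vectors <- function(n, k, sd_target, sec_target) {
  y <- seq_len(n)
  y <- (y - mean(y)) / sd(y) * sd_target + 10 * sd_target
  e <- numeric(n)
  e[1] <- sec_target * sqrt(n - k - 1)
  list(y_ref = y, y_fit = y - e, n_factors = k)
}
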