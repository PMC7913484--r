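test_that("fit_lda separates well-separated groups and obeys dimensionality", {
  set.seed(50)
  x <- data.frame(v = c(rnorm(100, 0), rnorm(100, 10)))
  lab <- rep(c("a", "b"), each = 100)
  m <- fit_lda(x, lab)
  expect_equal(length(m$eigenvalues), 1)
  acc <- mean(as.character(classify(m, x)$labels) == lab)
  expect_gte(acc, 0.99)

  # m = min(g - 1, p): six groups, 15 predictors -> 5 functions
  set.seed(51)
  x6 <- as.data.frame(matrix(rnorm(120 * 15), 120, 15))
  lab6 <- rep(letters[1:6], each = 20)
  x6[, 1] <- x6[, 1] + as.integer(factor(lab6))
  m6 <- fit_lda(x6, lab6)
  expect_equal(length(m6$eigenvalues), 5)
  expect_true(all(diff(m6$eigenvalues) <= 1e-10))
})

test_that("canonical scores have unit pooled within-group covariance", {
  set.seed(52)
  x <- as.data.frame(matrix(rnorm(90 * 6), 90, 6))
  lab <- rep(c("a", "b", "c"), each = 30)
  x[, 1] <- x[, 1] + 3 * as.integer(factor(lab))
  x[, 2] <- x[, 2] - 2 * as.integer(factor(lab))
  m <- fit_lda(x, lab)
  sc <- predict(m, x)
  g <- factor(lab)
  centered <- sc - rowsum(sc, g)[g, ] / as.vector(table(g))[g]
  Wcov <- crossprod(centered) / (90 - 3)
  expect_equal(unname(Wcov), diag(ncol(sc)), tolerance = 1e-6)
  # between-group scatter of scores is diagonal with the eigenvalues
  means <- rowsum(sc, g) / as.vector(table(g))
  B <- crossprod(sweep(means, 2, colMeans(sc)) * sqrt(as.vector(table(g))))
  expect_equal(unname(diag(B) / (90 - 3)), unname(m$eigenvalues),
               tolerance = 1e-6)
})

test_that("classification is affine-invariant and respects priors", {
  set.seed(53)
  x <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
  lab <- rep(c("a", "b", "c"), each = 20)
  x[, 1] <- x[, 1] + 2 * as.integer(factor(lab))
  m <- fit_lda(x, lab)
  p1 <- classify(m, x)$labels
  # rescale and shift every variable
  x2 <- sweep(sweep(x, 2, c(2, 0.5, 10, 4), "*"), 2, c(1, -3, 100, 0), "+")
  m2 <- fit_lda(x2, lab)
  expect_equal(as.character(classify(m2, x2)$labels), as.character(p1))
  # a training centroid classifies to its own group under equal priors
  meq <- fit_lda(x, lab, priors = "equal")
  cent_raw <- aggregate(x, list(lab), mean)
  pred_cent <- classify(meq, cent_raw[, -1])$labels
  expect_equal(as.character(pred_cent), cent_raw[, 1])
  # an overwhelming prior dominates
  mpr <- fit_lda(x, lab, priors = c(a = 1e-9, b = 1e-9, c = 1 - 2e-9))
  expect_true(all(classify(mpr, x)$labels == "c"))
})

test_that("collinear predictors trigger the singularity path, ridge recovers", {
  set.seed(54)
  x <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
  names(x) <- c("p1", "p2", "p3")
  x$p4 <- x$p1
  lab <- rep(c("a", "b"), each = 20)
  expect_error(fit_lda(x, lab), "collinear")
  expect_warning(m <- fit_lda(x, lab, ridge = 1e-8), "ridge")
  expect_s3_class(m, "lda_model")
  expect_error(predict(m, x[, 1:3]), "missing variable.*p4")
})

test_that("fit_lda agrees with MASS::lda classifications", {
  set.seed(55)
  x <- as.data.frame(matrix(rnorm(150 * 5), 150, 5))
  lab <- rep(c("a", "b", "c"), each = 50)
  x[, 1] <- x[, 1] + 1.5 * as.integer(factor(lab))
  x[, 3] <- x[, 3] - as.integer(factor(lab))
  ours <- classify(fit_lda(x, lab), x)$labels
  mass <- predict(MASS::lda(x, grouping = lab))$class
  expect_gte(mean(as.character(ours) == as.character(mass)), 0.99)
})

test_that("function diagnostics satisfy their algebraic identities", {
  d <- function_diagnostics(c(2.2, 0.7, 0.1), N = 60, p = 8, g = 4)
  expect_equal(sum(d$relative_pct), 100)
  # Wilks recurrence
  for (k in 1:2)
    expect_equal(d$wilks_lambda[k], d$wilks_lambda[k + 1] / (1 + d$eigenvalue[k]),
                 tolerance = 1e-12)
  expect_equal(d$canonical_correlation,
               sqrt(d$eigenvalue / (1 + d$eigenvalue)))
  expect_equal(d$df, (8 - 1:3 + 1) * (4 - 1:3))
  expect_true(all(diff(d$df) < 0))
  # zero eigenvalue limit
  d0 <- function_diagnostics(0, N = 50, p = 3, g = 2)
  expect_equal(d0$wilks_lambda, 1)
  expect_equal(d0$chi_square, 0)
})

test_that("confusion_report recomputes published-style rates from counts", {
  lv <- labels_from_counts(printed_confusion())
  cr <- confusion_report(lv$true, lv$pred)
  expect_equal(unname(rowSums(cr$matrix)),
               unname(c(5, 22, 9, 10, 18, 36)))
  expect_equal(round(cr$per_class_correct_pct[["honeydew"]], 1), 83.3)
  expect_equal(cr$per_class_correct_pct[["eucalyptus"]], 100)
  expect_equal(cr$overall_correct_pct, 100 * sum(diag(cr$matrix)) / cr$N)
  # all-correct predictions
  all_ok <- confusion_report(lv$true, lv$true)
  expect_equal(all_ok$overall_correct_pct, 100)
  expect_true(all(all_ok$matrix[upper.tri(all_ok$matrix)] == 0))
  expect_error(confusion_report(lv$true, rep("nonsense", length(lv$true))),
               "outside the true class set")
})
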