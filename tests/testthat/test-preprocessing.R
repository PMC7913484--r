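test_that("SNV centers and scales each spectrum", {
  wl <- c(1000, 1006, 1012)
  s <- spectra_set(rbind(c(2, 4, 6)), wl)
  expect_equal(unname(snv(s)$values[1, ]), c(-1, 0, 1))

  x <- make_spectra(8, 30, seed = 2)
  out <- snv(x)$values
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))
  # idempotence
  expect_equal(snv(snv(x))$values, snv(x)$values, tolerance = 1e-12)
  # constant spectrum errors
  flat <- spectra_set(rbind(c(1, 1, 1)), wl)
  expect_error(snv(flat), "degenerate")
})

test_that("MSC inverts per-row affine distortion against the reference", {
  x <- make_spectra(6, 25, seed = 4)
  ref <- colMeans(x$values)
  m1 <- msc(x, reference = ref)
  # a row equal to the reference is unchanged
  xr <- set_values(x[1], rbind(ref))
  expect_equal(unname(msc(xr, reference = ref)$values[1, ]), unname(ref),
               tolerance = 1e-10)
  # a row = 2*ref + 1 maps back to the reference
  x2 <- set_values(x[1], rbind(2 * ref + 1))
  expect_equal(unname(msc(x2, reference = ref)$values[1, ]), unname(ref),
               tolerance = 1e-10)
  # the fitted (a, b) match an explicit normal-equations solve
  for (i in 1:3) {
    row <- x$values[i, ]
    fit <- lm(row ~ ref)
    a <- coef(fit)[1]; b <- coef(fit)[2]
    expect_equal(unname(m1$values[i, ]), unname((row - a) / b),
                 tolerance = 1e-10)
  }
  expect_error(msc(x, reference = rep(1, 25)), "zero-variance")
})

test_that("detrend removes polynomial baselines exactly", {
  wl <- seq(1000, 1100, length.out = 21)
  const <- spectra_set(rbind(rep(3, 21)), wl)
  expect_true(all(abs(detrend(const)$values) < 1e-9))
  quad <- spectra_set(rbind(2 + 0.01 * wl - 1e-5 * wl^2), wl)
  expect_true(all(abs(detrend(quad)$values) < 1e-9))
  # residual orthogonal to the {1, wl, wl^2} basis
  x <- make_spectra(5, 21, seed = 5)
  x$wavelengths <- wl
  out <- detrend(x)$values
  for (basis in list(rep(1, 21), wl, wl^2)) {
    expect_true(all(abs(out %*% (basis / sqrt(sum(basis^2)))) < 1e-8))
  }
})

test_that("gap-segment derivative follows the 4-digit code", {
  wl <- seq(1000, 1000 + 6 * 39, by = 6)
  const <- spectra_set(rbind(rep(2.5, 40)), wl)
  d <- gap_segment_derivative(const, 1, 4, 4, 1)
  expect_true(all(abs(d$values) < 1e-12))
  # linear ramp, code (1,g,1,1) -> constant k*g
  k <- 0.37
  ramp <- spectra_set(rbind(k * seq_len(40)), wl)
  for (g in c(2, 4, 7)) {
    d <- gap_segment_derivative(ramp, 1, g, 1, 1)
    expect_true(all(abs(d$values - k * g) < 1e-10))
    expect_equal(length(d$wavelengths), 40 - g)
  }
  # (0,1,1,1) is the identity
  x <- make_spectra(4, 40, seed = 6)
  expect_equal(gap_segment_derivative(x, 0, 1, 1, 1)$values, x$values)
  # footprint larger than the axis errors with the minimum channel count
  short <- make_spectra(2, 5, seed = 7)
  expect_error(gap_segment_derivative(short, 2, 10, 10, 1), "at least")
})

test_that("derivative operator is linear", {
  x <- make_spectra(2, 40, seed = 8)
  a <- 1.7; b <- -0.6
  combo <- set_values(x, rbind(a * x$values[1, ] + b * x$values[2, ],
                               x$values[2, ]))
  t1 <- gap_segment_derivative(x, 1, 4, 4, 2)$values
  tc <- gap_segment_derivative(combo, 1, 4, 4, 2)$values
  expect_equal(tc[1, ], a * t1[1, ] + b * t1[2, ], tolerance = 1e-10)
})

test_that("treatment strings parse, format and apply correctly", {
  tr <- parse_treatment("Detrend only 1,4,4,1")
  expect_equal(tr$scatter, "Detrend only")
  expect_equal(c(tr$d, tr$g, tr$s1, tr$s2), c(1, 4, 4, 1))
  expect_equal(format(tr), "Detrend only 1,4,4,1")
  expect_equal(format(parse_treatment("SNV-DT 2,8,6,1")), "SNV-DT 2,8,6,1")
  expect_error(parse_treatment("Fancy 1,4,4,1"), "unknown scatter")
  expect_error(parse_treatment("SNV"), "cannot parse")

  x <- make_spectra(5, 40, seed = 9)
  expect_equal(apply_treatment(x, "None 0,0,1,1")$values, x$values)
  # SNV-DT d,g,s1,s2 equals the explicit composition
  lhs <- apply_treatment(x, "SNV-DT 1,4,4,1")$values
  rhs <- gap_segment_derivative(detrend(snv(x)), 1, 4, 4, 1)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("transforms are row-wise independent and affine-invariant", {
  x <- make_spectra(6, 40, seed = 10)
  perm <- c(4, 1, 6, 2, 5, 3)
  xp <- x[perm]
  for (tr in c("SNV 0,0,1,1", "Detrend only 1,4,4,1", "None 2,4,4,1")) {
    expect_equal(unname(apply_treatment(xp, tr)$values),
                 unname(apply_treatment(x, tr)$values[perm, ]),
                 tolerance = 1e-12)
  }
  # per-row affine distortion: SNV output unchanged; MSC with a fixed
  # reference maps original and distorted rows to the same output
  set.seed(11)
  a <- rnorm(6, 0, 0.2); b <- runif(6, 0.5, 2)
  xd <- set_values(x, x$values * b + a)
  expect_equal(snv(xd)$values, snv(x)$values, tolerance = 1e-9)
  ref <- colMeans(x$values)
  expect_equal(msc(xd, reference = ref)$values, msc(x, reference = ref)$values,
               tolerance = 1e-9)
})
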