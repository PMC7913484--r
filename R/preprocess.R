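#' Standard normal variate (SNV)
#'
#' Centers every spectrum to mean 0 and scales it to unit standard deviation
#' (n - 1 denominator). SNV removes per-sample additive offsets and
#' multiplicative scatter, the dominant particle-size artefacts in diffuse
#' reflectance.
#'
#' @param spectra a `spectra_set`.
#' @return a `spectra_set` of the same shape.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  x <- spectra$values
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  deg <- which(sdv == 0 | !is.finite(sdv))
  if (length(deg) > 0)
    stop("degenerate (constant) spectrum: ",
         paste(spectra$sample_ids[deg], collapse = ", "))
  set_values(spectra, (x - mu) / sdv)
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, x = a + b * ref + e, and replaced by (x - a) / b. The reference
#' defaults to the mean spectrum of the set; passing a fixed reference makes
#' the transform reusable on new samples.
#'
#' @param spectra a `spectra_set`.
#' @param reference optional numeric vector, one value per channel.
#' @return a `spectra_set`; the reference used is attached as attribute
#'   `"msc_reference"`.
#' @export
msc <- function(spectra, reference = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  x <- spectra$values
  if (is.null(reference)) reference <- colMeans(x)
  if (length(reference) != ncol(x))
    stop("reference length does not match channel count")
  rc <- reference - mean(reference)
  den <- sum(rc^2)
  if (den == 0) stop("zero-variance MSC reference spectrum")
  # per-row OLS of x on reference: b = cov(x, ref)/var(ref), a = mean(x) - b*mean(ref)
  b <- as.numeric(x %*% rc) / den
  a <- rowMeans(x) - b * mean(reference)
  out <- set_values(spectra, (x - a) / b)
  attr(out, "msc_reference") <- reference
  out
}

#' Detrend (polynomial baseline removal)
#'
#' Each spectrum is replaced by its residual from a least-squares polynomial
#' of degree `order` fitted on the wavelength axis. Order 2 is the standard
#' Barnes detrend used after (or instead of) SNV to remove curvilinear
#' baseline drift.
#'
#' @param spectra a `spectra_set`.
#' @param order polynomial degree (default 2).
#' @return a `spectra_set` of the same shape.
#' @export
detrend <- function(spectra, order = 2) {
  stopifnot(inherits(spectra, "spectra_set"))
  p <- length(spectra$wavelengths)
  if (p <= order) stop("need more channels (", p, ") than polynomial order ", order)
  basis <- stats::poly(spectra$wavelengths, degree = order, raw = FALSE)
  basis <- cbind(1, basis)
  q <- qr.Q(qr(basis))
  x <- spectra$values
  set_values(spectra, x - (x %*% q) %*% t(q))
}

boxcar_smooth <- function(x, s) {
  # centered running mean of width s on the columns-of-one-row vector x;
  # edges are dropped (no padding), so length shrinks by s - 1
  if (s == 1) return(x)
  n <- length(x)
  if (n < s) stop("need at least ", s, " channels for smoothing width ", s)
  cs <- cumsum(c(0, x))
  (cs[(s + 1):(n + 1)] - cs[1:(n - s + 1)]) / s
}

#' Gap-segment derivative with the 4-digit code
#'
#' Applies the WinISI-style treatment "d,g,s1,s2": a centered boxcar smooth
#' of width `s1`, then `d` successive gap differences (each output point is
#' the difference of the two smoothed values `g` channels apart), then a
#' second boxcar smooth of width `s2`. Code `0,*,1,1` is the identity;
#' `d = 0` smooths only. Output channels without full support are dropped and
#' the wavelength axis shrinks accordingly, so no boundary values are
#' fabricated.
#'
#' For a gap g, the difference at position i is x[i + ceiling(g/2)] -
#' x[i - floor(g/2)]: on a linear ramp x_i = k * i the first derivative is
#' the constant k * g.
#'
#' @param spectra a `spectra_set`.
#' @param d derivative order (>= 0).
#' @param g gap in channels (>= 1 when d >= 1).
#' @param s1,s2 boxcar widths for the first and second smooth (1 = none).
#' @return a `spectra_set` on a (possibly) truncated wavelength axis.
#' @export
gap_segment_derivative <- function(spectra, d, g, s1 = 1, s2 = 1) {
  stopifnot(inherits(spectra, "spectra_set"))
  d <- as.integer(d); g <- as.integer(g)
  s1 <- max(1L, as.integer(s1)); s2 <- max(1L, as.integer(s2))
  if (d < 0) stop("derivative order d must be >= 0")
  if (d >= 1 && g < 1) stop("gap g must be >= 1 when d >= 1")
  n <- length(spectra$wavelengths)
  need <- (s1 - 1) + d * g + (s2 - 1) + 1
  if (n < need)
    stop("treatment ", d, ",", g, ",", s1, ",", s2, " needs at least ",
         need, " channels, have ", n)

  smooth_axis <- function(w, s) {
    if (s == 1) return(w)
    lo <- floor((s - 1) / 2); hi <- s - 1 - lo
    w[(1 + lo):(length(w) - hi)]
  }
  diff_axis <- function(w, g) {
    lo <- floor(g / 2); hi <- g - lo
    w[(1 + lo):(length(w) - hi)]
  }
  apply_rows <- function(m, f) t(apply(m, 1, f))

  x <- spectra$values
  w <- spectra$wavelengths
  if (s1 > 1) {
    x <- apply_rows(x, function(r) boxcar_smooth(r, s1))
    w <- smooth_axis(w, s1)
  }
  if (d >= 1) {
    for (k in seq_len(d)) {
      m <- ncol(x)
      x <- x[, (1 + g):m, drop = FALSE] - x[, 1:(m - g), drop = FALSE]
      w <- diff_axis(w, g)
    }
  }
  if (s2 > 1) {
    x <- apply_rows(x, function(r) boxcar_smooth(r, s2))
    w <- smooth_axis(w, s2)
  }
  set_values(spectra, x, w)
}

scatter_levels <- c("None", "SNV", "MSC", "Detrend only", "SNV-DT")

#' Construct a mathematical treatment
#'
#' A treatment couples a scatter correction (`"None"`, `"SNV"`, `"MSC"`,
#' `"Detrend only"`, `"SNV-DT"`) with a 4-digit derivative code
#' `d,g,s1,s2`. The canonical string form, e.g. `"None 1,4,4,1"` or
#' `"SNV-DT 2,8,6,1"`, round-trips through [parse_treatment()] and
#' [format()].
#'
#' @param scatter scatter-correction name (one of the five tokens above).
#' @param d,g,s1,s2 derivative code digits; see [gap_segment_derivative()].
#' @return an object of class `math_treatment`.
#' @export
math_treatment <- function(scatter = "None", d = 0, g = 0, s1 = 1, s2 = 1) {
  scatter <- as.character(scatter)
  if (!scatter %in% scatter_levels)
    stop("unknown scatter correction '", scatter, "'; expected one of: ",
         paste(scatter_levels, collapse = ", "))
  d <- as.integer(d); g <- as.integer(g)
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (d < 0 || (d >= 1 && g < 1) || s1 < 1 || s2 < 1)
    stop("invalid derivative code ", d, ",", g, ",", s1, ",", s2)
  structure(list(scatter = scatter, d = d, g = g, s1 = s1, s2 = s2),
            class = "math_treatment")
}

#' Parse a treatment string
#'
#' @param x string like `"Detrend only 1,4,4,1"`.
#' @return a `math_treatment`.
#' @rdname math_treatment
#' @export
parse_treatment <- function(x) {
  if (inherits(x, "math_treatment")) return(x)
  x <- trimws(x)
  m <- regmatches(x, regexec("^(.*?)\\s+(\\d+),(\\d+),(\\d+),(\\d+)$", x))[[1]]
  if (length(m) != 6)
    stop("cannot parse treatment string '", x,
         "'; expected '<scatter> d,g,s1,s2'")
  math_treatment(m[2], as.integer(m[3]), as.integer(m[4]),
                 as.integer(m[5]), as.integer(m[6]))
}

#' @export
format.math_treatment <- function(x, ...) {
  paste0(x$scatter, " ", x$d, ",", x$g, ",", x$s1, ",", x$s2)
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("<math_treatment> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Apply a mathematical treatment to spectra
#'
#' The scatter correction is applied first, then the gap-segment derivative
#' code. `"SNV-DT"` is SNV followed by detrend. For `"MSC"` a fixed
#' reference may be supplied so calibration and prediction use the same
#' correction.
#'
#' @param spectra a `spectra_set`.
#' @param treatment a `math_treatment` or its string form.
#' @param msc_reference optional fixed MSC reference spectrum.
#' @return a transformed `spectra_set`.
#' @export
apply_treatment <- function(spectra, treatment, msc_reference = NULL) {
  tr <- parse_treatment(treatment)
  x <- switch(tr$scatter,
    "None" = spectra,
    "SNV" = snv(spectra),
    "MSC" = msc(spectra, reference = msc_reference),
    "Detrend only" = detrend(spectra),
    "SNV-DT" = detrend(snv(spectra))
  )
  ref <- attr(x, "msc_reference")
  if (tr$d > 0 || tr$s1 > 1 || tr$s2 > 1) {
    x <- gap_segment_derivative(x, tr$d, max(tr$g, 1L), tr$s1, tr$s2)
  }
  attr(x, "msc_reference") <- ref
  x
}
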