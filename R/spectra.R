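#' Spectra container
#'
#' A `spectra_set` holds a samples x channels matrix of diffuse-reflectance
#' NIR readings on a shared, strictly increasing wavelength axis, together
#' with an indicator of whether the values are raw reflectance (R) or the
#' absorbance-like working representation log10(1/R).
#'
#' @param values numeric matrix, samples in rows, wavelength channels in
#'   columns.
#' @param wavelengths numeric vector of channel wavelengths in nm, strictly
#'   increasing, one per column of `values`.
#' @param sample_ids character vector of sample identifiers, one per row.
#'   Defaults to rownames of `values` or `"S1"`, `"S2"`, ...
#' @param representation `"reflectance"` or `"absorbance"` (log(1/R)).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(values, wavelengths, sample_ids = NULL,
                        representation = c("absorbance", "reflectance")) {
  representation <- match.arg(representation)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  wavelengths <- as.numeric(wavelengths)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(wavelengths) != ncol(values))
    stop("wavelengths length (", length(wavelengths),
         ") does not match column count (", ncol(values), ")")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(values)) stop("spectra values contain missing entries")
  rownames(values) <- sample_ids
  colnames(values) <- format(wavelengths, trim = TRUE)
  structure(
    list(sample_ids = sample_ids, wavelengths = wavelengths,
         values = values, representation = representation),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", length(x$sample_ids), " samples x ",
      length(x$wavelengths), " channels (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)),
      " nm), representation: ", x$representation, "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$values)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param i row (sample) index, logical or integer or character ids.
#' @param ... unused.
#' @return a `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra_set(x$values[i, , drop = FALSE], x$wavelengths,
              x$sample_ids[i], x$representation)
}

#' Replace the value matrix of a spectra set
#'
#' Used by transforms that may shorten the wavelength axis (derivatives).
#' @param x a `spectra_set`.
#' @param values new matrix, same row count.
#' @param wavelengths new axis; default keeps the old one.
#' @return a `spectra_set`.
#' @keywords internal
set_values <- function(x, values, wavelengths = x$wavelengths) {
  spectra_set(values, wavelengths, x$sample_ids, x$representation)
}

#' Convert reflectance spectra to log10(1/R)
#'
#' Diffuse reflectance R in (0, 1] is converted to the absorbance-like
#' working representation log10(1/R) used throughout the calibration
#' workflow; a white reference has R = 1 and maps to 0.
#'
#' @param spectra a `spectra_set` with `representation = "reflectance"`.
#' @return a `spectra_set` in absorbance representation.
#' @export
to_log_inv_reflectance <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (spectra$representation != "reflectance")
    stop("spectra are already in absorbance (log(1/R)) representation")
  bad <- which(spectra$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive reflectance for sample '",
         spectra$sample_ids[bad[1, 1]], "' at ",
         format(spectra$wavelengths[bad[1, 2]]), " nm")
  }
  out <- spectra
  out$values[] <- log10(1 / spectra$values)
  out$representation <- "absorbance"
  out
}

#' Read spectra from a wide CSV file
#'
#' Expected layout: first column `sample_id`, remaining columns named by
#' wavelength in nm (numeric column names), one row per sample.
#'
#' @param path CSV file path.
#' @param representation value representation stored in the file.
#' @return a `spectra_set`.
#' @export
read_spectra_csv <- function(path, representation = "absorbance") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id")
    stop("first column of a spectra CSV must be 'sample_id'")
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl)) stop("spectra CSV columns after sample_id must be numeric wavelengths")
  spectra_set(as.matrix(df[, -1, drop = FALSE]), wl, df$sample_id, representation)
}

#' Write spectra to a wide CSV file
#'
#' @param spectra a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(sample_id = spectra$sample_ids, check.names = FALSE)
  m <- as.data.frame(spectra$values)
  names(m) <- format(spectra$wavelengths, trim = TRUE)
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}
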