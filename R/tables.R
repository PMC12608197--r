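#' Per-sample spectra table
#'
#' The X matrix of a chemometric calibration: one row per sample, one column
#' per spectral channel, tied to a [wavelength_grid()] and optional sample
#' metadata (growth stage, treatment, leaf position, ...).
#'
#' @param reflectance Numeric n x p matrix, no missing values.
#' @param grid A [wavelength_grid()] with p centers.
#' @param meta Optional data frame with n rows of sample metadata.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(reflectance, grid, meta = NULL) {
  reflectance <- as.matrix(reflectance)
  if (!inherits(grid, "wavelength_grid")) stopf("`grid` must be a wavelength_grid")
  if (ncol(reflectance) != length(grid$centers))
    stopf("spectra have %d channels but grid has %d", ncol(reflectance),
          length(grid$centers))
  if (anyNA(reflectance)) stopf("spectra table must not contain missing values")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != nrow(reflectance))
      stopf("metadata rows (%d) do not match samples (%d)", nrow(meta),
            nrow(reflectance))
  }
  structure(list(reflectance = reflectance, grid = grid, meta = meta),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d samples x %d channels (%.1f-%.1f nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$grid$centers), max(x$grid$centers)))
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$reflectance)

#' Analyte reference values
#'
#' The Y vector of a calibration: one laboratory reference value per sample.
#'
#' @param values Numeric vector of finite analyte values.
#' @param analyte Analyte name, e.g. `"nitrogen"` or `"chlorophyll"`.
#' @param units Measurement units, e.g. `"%"` or `"mg/g"`.
#' @return An object of class `response_vector`.
#' @export
response_vector <- function(values, analyte = "nitrogen", units = "%") {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stopf("response values must be finite")
  structure(list(values = values, analyte = analyte, units = units),
            class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  cat(sprintf("<response_vector> %s [%s], n = %d, range %.4f-%.4f\n",
              x$analyte, x$units, length(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' @export
length.response_vector <- function(x) length(x$values)

# Coerce spectra_table | matrix to plain matrix.
as_X <- function(x) {
  if (inherits(x, "spectra_table")) x$reflectance else as.matrix(x)
}

# Coerce response_vector | numeric to plain numeric vector.
as_y <- function(y) {
  if (inherits(y, "response_vector")) y$values else as.numeric(y)
}
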