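#' Spectral preprocessing steps and pipelines
#'
#' A preprocessing pipeline is an ordered list of per-spectrum steps, applied
#' row-wise to a [spectra_table()] (and identically to pixel spectra during
#' mapping). Three steps are available:
#'
#' * `step_sg()` -- Savitzky-Golay convolution smoothing, removing
#'   high-frequency sensor noise (local least-squares polynomial refit).
#' * `step_snv()` -- standard normal variate, removing multiplicative
#'   scatter from leaf glossiness and surface geometry.
#' * `step_detrend()` -- subtraction of a global least-squares polynomial
#'   baseline over the wavelength axis, removing diffuse-reflection drift.
#'
#' `default_preprocess()` is the S-G (order 1, window 5), SNV, detrend
#' (order 2) sequence used throughout the package.
#'
#' @param order Polynomial order.
#' @param window Odd window length, `window > order`. For `step_detrend` the
#'   fit is global; the window argument is accepted for configuration
#'   parity with instrument software and ignored.
#' @return A step object, or for `preprocess_spec` / `default_preprocess`
#'   an object of class `preprocess_spec`.
#' @name preprocessing
NULL

#' @rdname preprocessing
#' @export
step_sg <- function(order = 1, window = 5) {
  check_sg_window(order, window)
  structure(list(kind = "sg", order = order, window = window),
            class = "preprocess_step")
}

#' @rdname preprocessing
#' @export
step_snv <- function() structure(list(kind = "snv"), class = "preprocess_step")

#' @rdname preprocessing
#' @export
step_detrend <- function(order = 2, window = 5) {
  if (order < 0 || order != floor(order)) stopf("detrend order must be a non-negative integer")
  structure(list(kind = "detrend", order = order, window = window),
            class = "preprocess_step")
}

#' @rdname preprocessing
#' @param ... `preprocess_step` objects in application order.
#' @export
preprocess_spec <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1]]) &&
      !inherits(steps[[1]], "preprocess_step"))
    steps <- steps[[1]]
  for (s in steps)
    if (!inherits(s, "preprocess_step")) stopf("all pipeline entries must be preprocess steps")
  structure(steps, class = "preprocess_spec")
}

#' @rdname preprocessing
#' @export
default_preprocess <- function() {
  preprocess_spec(step_sg(order = 1, window = 5), step_snv(),
                  step_detrend(order = 2, window = 5))
}

#' @export
print.preprocess_spec <- function(x, ...) {
  if (length(x) == 0) { cat("<preprocess_spec> identity\n"); return(invisible(x)) }
  cat("<preprocess_spec>",
      paste(vapply(x, function(s) s$kind, ""), collapse = " -> "), "\n")
  invisible(x)
}

check_sg_window <- function(order, window) {
  if (window %% 2 != 1) stopf("window length must be odd (got %d)", window)
  if (window <= order) stopf("window length (%d) must exceed polynomial order (%d)",
                             window, order)
  invisible(TRUE)
}

#' Savitzky-Golay smoothing of one spectrum
#'
#' Each point is replaced by the center value of a local least-squares
#' polynomial fit; edge points come from polynomial fits of the terminal
#' windows.
#'
#' @param x Numeric spectrum, `length(x) >= window`.
#' @param order Polynomial order.
#' @param window Odd window length greater than `order`.
#' @return Smoothed spectrum of the same length.
#' @export
savgol_smooth <- function(x, order = 1, window = 5) {
  check_sg_window(order, window)
  if (length(x) < window)
    stopf("spectrum length (%d) must be at least the window length (%d)",
          length(x), window)
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Standard normal variate transform of one spectrum
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation; the
#' output has mean 0 and SD 1 and is invariant to affine rescaling of the
#' input.
#'
#' @param x Numeric spectrum with positive standard deviation.
#' @return Standardized spectrum.
#' @export
snv <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("SNV undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Detrend one spectrum by global polynomial baseline removal
#'
#' Fits a least-squares polynomial of the given order over the wavelength
#' axis and subtracts it, removing baseline drift from diffuse reflection.
#'
#' @param x Numeric spectrum, `length(x) > order`.
#' @param order Baseline polynomial order.
#' @param window Ignored (kept for configuration parity).
#' @param wavelengths Abscissa for the fit; defaults to the channel index.
#' @return Baseline-corrected spectrum (residuals of the fit).
#' @export
detrend <- function(x, order = 2, window = NULL, wavelengths = NULL) {
  n <- length(x)
  if (n <= order) stopf("spectrum length (%d) must exceed the baseline order (%d)",
                        n, order)
  lam <- wavelengths %||% seq_len(n)
  lam <- (lam - mean(lam)) / max(sd(lam), 1e-12)  # condition the basis
  basis <- outer(lam, 0:order, `^`)
  as.numeric(x - basis %*% qr.solve(basis, x))
}

apply_steps <- function(x, spec, wavelengths = NULL) {
  for (s in spec) {
    x <- switch(s$kind,
                sg = savgol_smooth(x, s$order, s$window),
                snv = snv(x),
                detrend = detrend(x, s$order, wavelengths = wavelengths),
                stopf("unknown preprocessing step '%s'", s$kind))
  }
  x
}

#' Apply a preprocessing pipeline to every spectrum of a table
#'
#' Steps are applied in listed order, independently to each row (no
#' cross-sample leakage); the wavelength grid is unchanged.
#'
#' @param table A [spectra_table()] (or plain matrix).
#' @param spec A [preprocess_spec()]; an empty spec is the identity.
#' @return Object of the same class as `table`.
#' @export
apply_pipeline <- function(table, spec) {
  if (!inherits(spec, "preprocess_spec")) stopf("`spec` must be a preprocess_spec")
  X <- as_X(table)
  lam <- if (inherits(table, "spectra_table")) table$grid$centers else NULL
  if (length(spec) > 0)
    X <- t(apply(X, 1, apply_steps, spec = spec, wavelengths = lam))
  if (inherits(table, "spectra_table"))
    spectra_table(X, table$grid, table$meta)
  else X
}
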