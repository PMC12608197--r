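#' Fit a partial least squares regression model
#'
#' Deterministic SIMPLS fit on mean-centered data (no variance scaling:
#' spectral preprocessing already handles scale). Prediction is
#' `y_hat = (x - x_mean) . beta + y_mean`.
#'
#' @param X Calibration spectra, [spectra_table()] or matrix (n x p).
#' @param y Calibration responses, [response_vector()] or numeric (non
#'   constant).
#' @param ncomp Number of latent variables, `1 <= ncomp <= min(n - 1, p)`.
#' @param channels Integer channel labels of the columns of `X` within the
#'   modelling window (defaults to `1:p`); carried for bookkeeping and
#'   pixel-wise mapping.
#' @param wavelengths Optional nm centers of the columns, for reporting.
#' @return An object of class `plsr_model` with fields `coefficients`,
#'   `intercept`, `x_mean`, `y_mean`, `ncomp`, `channels`, `wavelengths` and
#'   the full coefficient path `coef_path` (p x ncomp).
#' @export
fit_plsr <- function(X, y, ncomp, channels = NULL, wavelengths = NULL) {
  X <- as_X(X); y <- as_y(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("X and y disagree on sample count")
  if (sd(y) == 0) stopf("PLSR undefined for a constant response")
  if (!is_count(ncomp) || ncomp > min(n - 1, p))
    stopf("ncomp must be an integer in [1, min(n - 1, p)] = [1, %d]", min(n - 1, p))
  fit <- .simpls_path(X, y, as.integer(ncomp))
  beta <- fit$B[, ncomp]
  if (!all(is.finite(beta))) stopf("PLSR produced non-finite coefficients")
  structure(list(coefficients = beta,
                 intercept = fit$y_mean - sum(fit$x_mean * beta),
                 x_mean = as.numeric(fit$x_mean), y_mean = fit$y_mean,
                 ncomp = as.integer(ncomp),
                 channels = as.integer(channels %||% seq_len(p)),
                 wavelengths = wavelengths,
                 coef_path = fit$B),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d channels, %d latent variables\n",
              length(x$coefficients), x$ncomp))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' @param object A [fit_plsr()] model.
#' @param newdata [spectra_table()] or matrix whose columns are either the
#'   model's training channels (p columns) or a full window from which the
#'   model's `channels` are extracted.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- as_X(newdata)
  p <- length(object$coefficients)
  if (ncol(X) != p) {
    if (max(object$channels) <= ncol(X))
      X <- X[, object$channels, drop = FALSE]
    else
      stopf("newdata has %d columns; model needs its %d training channels",
            ncol(X), p)
  }
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' Serialize / restore a PLSR model as JSON
#'
#' Stores the channel subset, coefficients, centering means, intercept and
#' component count -- everything prediction needs.
#'
#' @param model A [fit_plsr()] model.
#' @param path JSON file path.
#' @return `write_plsr_json` returns `path` invisibly; `read_plsr_json` the
#'   restored model (without the coefficient path).
#' @export
write_plsr_json <- function(model, path) {
  jsonlite::write_json(list(coefficients = model$coefficients,
                            intercept = model$intercept,
                            x_mean = model$x_mean, y_mean = model$y_mean,
                            ncomp = model$ncomp, channels = model$channels,
                            wavelengths = model$wavelengths),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plsr_json
#' @export
read_plsr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$channels <- as.integer(obj$channels)
  structure(obj, class = "plsr_model")
}

#' Cross-validation fold assignment
#'
#' Contiguous blocks of a seeded shuffle: samples are permuted once, then cut
#' into `folds` nearly equal blocks. Deterministic given `seed`.
#'
#' @param n Number of samples.
#' @param folds Number of folds, `folds <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
cv_folds <- function(n, folds = 10, seed = 1) {
  if (folds > n) stopf("more folds (%d) than samples (%d)", folds, n)
  ord <- with_seed(seed, sample.int(n))
  sizes <- rep(floor(n / folds), folds)
  sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1L
  fold <- integer(n)
  fold[ord] <- rep(seq_len(folds), sizes)
  fold
}

# RMSE_CV per component count 1..maxk for a fixed fold assignment.
rmse_cv_path <- function(X, y, fold, maxk) {
  ntr_min <- length(y) - max(tabulate(fold))
  maxk <- max(1L, min(maxk, ncol(X), ntr_min - 1L))
  as.numeric(.cv_rmse_path(as.matrix(X), y, as.integer(fold), as.integer(maxk)))
}

# Scalar RMSE_CV of a channel subset: the minimum over component counts.
rmsecv <- function(X, y, cols, fold, maxk) {
  min(rmse_cv_path(X[, cols, drop = FALSE], y, fold, maxk))
}

#' Choose the number of latent variables by 10-fold cross-validation
#'
#' @param X,y Calibration data as in [fit_plsr()].
#' @param max_components Largest component count examined (capped at
#'   `min(n - 1, p)`); defaults to 10.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold shuffle.
#' @return List with `best_k` (argmin of RMSE_CV, first minimum on ties) and
#'   `rmse_cv` (per-k error trace).
#' @export
cv_select_components <- function(X, y, max_components = 10, folds = 10, seed = 1) {
  X <- as_X(X); y <- as_y(y)
  n <- nrow(X)
  if (folds > n) stopf("more folds (%d) than samples (%d)", folds, n)
  fold <- cv_folds(n, folds, seed)
  path <- rmse_cv_path(X, y, fold, max_components)
  list(best_k = which.min(path), rmse_cv = path)
}

#' Model performance metrics: R, RMSE, RPD
#'
#' Computes the correlation coefficient `R = cor(y_hat, y)`, the root mean
#' squared error `RMSE = sqrt(mean((y_hat - y)^2))` in analyte units, and
#' the residual prediction deviation `RPD = sd(y) / RMSE` (sample SD, n-1);
#' RPD > 2 conventionally indicates a usable quantitative model.
#'
#' @param model A [fit_plsr()] model.
#' @param X,y Evaluation set (at least 2 samples).
#' @param label Set label, `"calibration"` or `"prediction"`.
#' @return A one-row data frame of class `metrics_report` with columns
#'   `set`, `n`, `R`, `RMSE`, `RPD`. A zero RMSE yields `RPD = Inf`; a
#'   constant prediction yields `R = NA` with a warning.
#' @export
evaluate <- function(model, X, y, label = "prediction") {
  X <- as_X(X); y <- as_y(y)
  if (length(y) < 2) stopf("R and RPD need at least 2 samples")
  yhat <- predict(model, X)
  rmse <- sqrt(mean((yhat - y)^2))
  r <- if (sd(yhat) == 0) {
    warning("constant predictions: R undefined")
    NA_real_
  } else cor(yhat, y)
  rpd <- if (rmse == 0) Inf else sd(y) / rmse
  structure(data.frame(set = label, n = length(y), R = r, RMSE = rmse,
                       RPD = rpd),
            class = c("metrics_report", "data.frame"))
}
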