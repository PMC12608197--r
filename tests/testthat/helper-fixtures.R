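# Shared fixtures: everything is generated in code at test time.

# A reduced wavelength grid covering the modelling window: p uniformly spaced
# channels from 430 to 900 nm. Selector tests run on this grid so suites stay
# fast; the full 856-band grid is exercised where channel counts matter.
toy_grid <- function(p = 120) {
  wavelength_grid(seq(430, 900, length.out = p))
}

# Simulation config on the reduced grid with two planted absorption bands
# (479 and 689 nm, the shared nitrogen/chlorophyll diagnostics).
toy_config <- function(seed = 1, n = 150, p = 120, noise_sd = 0.002,
                       effect = 0.01, width = 15) {
  simulation_config(seed = seed, n_samples = n,
                    planted_bands = data.frame(center = c(479, 689),
                                               width = width,
                                               effect = effect),
                    noise_sd = noise_sd, grid = toy_grid(p))
}

toy_data <- function(seed = 1, n = 150, p = 120, ...) {
  sim <- simulate_spectra(toy_config(seed = seed, n = n, p = p, ...))
  list(X = sim$spectra$reflectance, y = sim$response$values,
       spectra = sim$spectra, response = sim$response,
       cfg = toy_config(seed = seed, n = n, p = p, ...))
}

# Low-dimensional regression fixture with a known planted structure:
# y is a noiseless (or noisy) linear function of `k` latent directions.
latent_data <- function(seed = 1, n = 60, p = 20, k = 3, noise = 0) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    scores <- matrix(rnorm(n * k), n, k)
    load <- matrix(rnorm(k * p), k, p)
    X <- scores %*% load
    y <- scores %*% seq_len(k) + if (noise > 0) rnorm(n, 0, noise) else 0
    list(X = X, y = as.numeric(y))
  })
}

# Independent manual 10-fold CV oracle (pure R, no package internals).
manual_cv_rmse <- function(X, y, fold, k) {
  errs <- numeric(0)
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    fit <- cfoselect::fit_plsr(X[tr, , drop = FALSE], y[tr], k)
    errs <- c(errs, (predict(fit, X[te, , drop = FALSE]) - y[te])^2)
  }
  sqrt(mean(errs))
}
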