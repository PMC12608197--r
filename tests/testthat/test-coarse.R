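# Fixture for coarse selectors: strong two-band signal on the reduced grid.
coarse_data <- function(seed) {
  toy_data(seed = seed, n = 120, p = 80, noise_sd = 0.002)
}

test_that("iRF recovers planted bands and rejects distant null channels", {
  hits <- null_rates <- numeric(0)
  for (seed in 1:5) {
    d <- coarse_data(seed)
    sel <- irf_select(d$X, d$y, n_iterations = 150, window_width = 6,
                      n_subintervals = 10, seed = seed)
    planted <- planted_channels(d$cfg)
    lam <- d$cfg$grid$centers
    far <- which(vapply(lam, function(l) all(abs(l - c(479, 689)) > 50), TRUE))
    hits <- c(hits, mean(planted %in% sel$channels))
    null_rates <- c(null_rates, mean(far %in% sel$channels))
  }
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(null_rates), 0.2)
})

test_that("iRF no-op search returns the initial equidistant interval set", {
  d <- coarse_data(1)
  sel <- irf_select(d$X, d$y, n_iterations = 0, window_width = 6,
                    n_subintervals = 10, seed = 1)
  starts <- unique(round(seq(1, 80 - 6 + 1, length.out = 10)))
  expect_identical(sel$channels,
                   sort(unique(unlist(lapply(starts, function(s) s:(s + 5))))))
})

test_that("iRF frequency threshold zero returns every channel", {
  d <- coarse_data(2)
  sel <- irf_select(d$X, d$y, n_iterations = 20, window_width = 6,
                    n_subintervals = 10, freq_threshold = 0, seed = 2)
  expect_identical(sel$channels, 1:80)
})

test_that("iRF is reproducible under a fixed seed", {
  d <- coarse_data(3)
  a <- irf_select(d$X, d$y, n_iterations = 60, window_width = 6,
                  n_subintervals = 10, seed = 7)
  b <- irf_select(d$X, d$y, n_iterations = 60, window_width = 6,
                  n_subintervals = 10, seed = 7)
  expect_identical(a$channels, b$channels)
  expect_identical(a$trace, b$trace)
})

test_that("iVISSA weights separate planted channels from distant nulls", {
  # flat-baseline, scatter-free fixture in the p > n regime: far-off
  # channels carry baseline + noise only, so they are genuinely null
  w_planted <- w_far <- hits <- nulls <- numeric(0)
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, n_samples = 60,
                             planted_bands = data.frame(center = c(479, 689),
                                                        width = 15,
                                                        effect = 0.01),
                             noise_sd = 0.01, scatter_sd = 0,
                             flat_baseline = TRUE, grid = toy_grid(150))
    sim <- simulate_spectra(cfg)
    sel <- ivissa_select(sim$spectra$reflectance, sim$response$values,
                         n_submodels = 150, n_rounds = 15, tol = 0.002,
                         seed = seed)
    planted <- planted_channels(cfg)
    lam <- cfg$grid$centers
    far <- which(vapply(lam, function(l) all(abs(l - c(479, 689)) > 50), TRUE))
    w_planted <- c(w_planted, mean(sel$weights[planted]))
    w_far <- c(w_far, mean(sel$weights[far]))
    hits <- c(hits, mean(planted %in% sel$channels))
    nulls <- c(nulls, mean(far %in% sel$channels))
  }
  expect_gt(mean(w_planted), 0.6)
  expect_lt(mean(w_far), 0.45)
  expect_gt(mean(w_planted) - mean(w_far), 0.2)
  expect_gt(mean(hits), mean(nulls))   # selection enriches planted channels
  expect_gte(mean(hits), 0.6)
  expect_lte(mean(nulls), 0.35)
})

test_that("iVISSA with unit weights and shrinkage disabled selects everything", {
  d <- coarse_data(4)
  sel <- ivissa_select(d$X, d$y, n_submodels = 20, w0 = 1, shrink = FALSE,
                       n_rounds = 2, seed = 1)
  expect_identical(sel$channels, 1:80)
})

test_that("duplicated planted channels are exchangeable substitutes", {
  # identical informative columns compete in the weight feedback: the
  # selection retains the signal through at least one copy in every run,
  # and the surviving copy carries the weight mass
  kept <- 0
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, n_samples = 60,
                             planted_bands = data.frame(center = c(479, 689),
                                                        width = 15,
                                                        effect = 0.01),
                             noise_sd = 0.01, scatter_sd = 0,
                             flat_baseline = TRUE, grid = toy_grid(150))
    sim <- simulate_spectra(cfg)
    ctr <- which.min(abs(cfg$grid$centers - 689))
    X2 <- cbind(sim$spectra$reflectance, sim$spectra$reflectance[, ctr])
    sel <- ivissa_select(X2, sim$response$values, n_submodels = 120,
                         n_rounds = 8, seed = seed)
    kept <- kept + any(c(ctr, 151L) %in% sel$channels)
    expect_gt(max(sel$weights[c(ctr, 151L)]), 0.6)
  }
  expect_gte(kept, 4)
})

test_that("coarse selections do not materially degrade prediction accuracy", {
  d <- coarse_data(6)
  X <- apply_pipeline(d$spectra, default_preprocess())$reflectance
  sp <- spxy_split(X, d$y, 3)
  Xc <- X[sp$calibration, ]; yc <- d$y[sp$calibration]
  Xp <- X[sp$prediction, ]; yp <- d$y[sp$prediction]
  full_k <- cv_select_components(Xc, yc, 10, seed = 1)$best_k
  full <- evaluate(fit_plsr(Xc, yc, full_k), Xp, yp)
  for (algo in c("irf", "ivissa")) {
    sel <- if (algo == "irf")
      irf_select(Xc, yc, n_iterations = 120, window_width = 6,
                 n_subintervals = 10, seed = 1)
    else ivissa_select(Xc, yc, n_submodels = 100, n_rounds = 6, seed = 1)
    expect_gt(length(sel$channels), 0)
    k <- cv_select_components(Xc[, sel$channels], yc,
                              min(10, length(sel$channels)), seed = 1)$best_k
    m <- fit_plsr(Xc[, sel$channels, drop = FALSE], yc, k,
                  channels = sel$channels)
    red <- evaluate(m, Xp[, sel$channels, drop = FALSE], yp)
    expect_lte(red$RMSE, full$RMSE * 1.05)
  }
})

test_that("a selection is produced whenever some channel is strongly correlated", {
  d <- coarse_data(8)
  r <- abs(apply(d$X, 2, cor, y = d$y))
  expect_gt(max(r), 0.5)
  sel <- irf_select(d$X, d$y, n_iterations = 80, window_width = 6,
                    n_subintervals = 10, seed = 3)
  expect_gt(length(sel$channels), 0)
})
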