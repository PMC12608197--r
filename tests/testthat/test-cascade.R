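# Reduced iteration budgets for cascade tests; algorithms unchanged.
small_config <- function() {
  cascade_config(
    irf = list(n_iterations = 60, window_width = 6, n_subintervals = 10),
    ivissa = list(n_submodels = 60, n_rounds = 4),
    cars = list(n_mc = 30),
    boss = list(n_bootstrap = 100, submodels_per_round = 50),
    vcpa = list(n_bms = 40, n_edf_iters = 4, final_pool = 10),
    iriv = list(n_submodels = 100),
    ga = list(n_evaluations = 80))
}

test_that("exactly twelve coarse-fine-optimal strategies are enumerated", {
  g <- strategy_grid()
  expect_equal(nrow(g), 12)
  expect_equal(nrow(unique(g[, c("coarse", "fine", "optimal")])), 12)
  expect_setequal(unique(g$coarse), c("iRF", "iVISSA"))
  expect_setequal(unique(g$fine), c("CARS", "BOSS", "VCPA"))
  expect_setequal(unique(g$optimal), c("IRIV", "GA"))
  expect_true("iRF-CARS-IRIV" %in% g$name)
})

test_that("a single strategy runs end-to-end with chained containment", {
  d <- toy_data(seed = 1, n = 100, p = 60)
  sp <- spxy_split(d$X, d$y, 3)
  res <- run_strategy(d$spectra, d$response, sp, "iRF-CARS-IRIV",
                      config = small_config(), seed = 1)
  sels <- res$selections
  expect_true(all(sels$optimal$channels %in% sels$fine$channels))
  expect_true(all(sels$fine$channels %in% sels$coarse$channels))
  expect_true(all(is.finite(as.matrix(res$metrics[, -(1:2)]))))
  expect_identical(res$metrics$stage, c("full", "coarse", "fine", "optimal"))
})

test_that("identical seeds reproduce an identical cascade", {
  d <- toy_data(seed = 2, n = 90, p = 50)
  sp <- spxy_split(d$X, d$y, 3)
  a <- run_strategy(d$X, d$y, sp, c("iVISSA", "BOSS", "GA"),
                    config = small_config(), seed = 5)
  b <- run_strategy(d$X, d$y, sp, c("iVISSA", "BOSS", "GA"),
                    config = small_config(), seed = 5)
  expect_identical(a$selections$optimal$channels, b$selections$optimal$channels)
  expect_identical(a$metrics, b$metrics)
  expect_error(run_strategy(d$X, d$y, sp, c("iRF", "CARS", "PSO"),
                            config = small_config()), "unknown strategy")
})

test_that("prediction rows never influence selection or calibration metrics", {
  d <- toy_data(seed = 3, n = 90, p = 50)
  sp <- spxy_split(d$X, d$y, 3)
  y2 <- d$y
  y2[sp$prediction] <- sample(y2[sp$prediction])  # shuffle prediction responses
  a <- run_strategy(d$X, d$y, sp, "iRF-VCPA-GA", config = small_config(), seed = 2)
  b <- run_strategy(d$X, y2, sp, "iRF-VCPA-GA", config = small_config(), seed = 2)
  expect_identical(a$selections$optimal$channels, b$selections$optimal$channels)
  expect_identical(a$metrics[, c("R_C", "RMSE_C", "RPD_C")],
                   b$metrics[, c("R_C", "RMSE_C", "RPD_C")])
})

test_that("run_all produces the twelve-strategy comparison table", {
  d <- toy_data(seed = 4, n = 90, p = 50)
  sp <- spxy_split(d$X, d$y, 3)
  out <- run_all(d$spectra, d$response, sp, config = small_config(), seed = 1)
  expect_length(out$results, 12)
  cmp <- out$comparison
  expect_equal(nrow(cmp), 12 * 4)  # full/coarse/fine/optimal per strategy
  expect_true(all(c("strategy", "stage", "NV", "NV_pct", "R_C", "RMSE_C",
                    "RPD_C", "R_P", "RMSE_P", "RPD_P", "best") %in% names(cmp)))
  expect_equal(cmp$NV_pct, round(100 * cmp$NV / 50, 2))
  expect_equal(sum(cmp$best), 1)
  best_row <- cmp[cmp$best, ]
  opt <- cmp[cmp$stage == "optimal", ]
  expect_equal(best_row$R_P, max(opt$R_P))
  # number of variables never grows along a chain and shrinks overall
  for (r in out$results) {
    nv <- r$metrics$NV
    expect_true(all(diff(nv) <= 0))
    expect_lt(nv[4], nv[1])
  }
})

test_that("wavelength bookkeeping reproduces the printed percentages", {
  expect_equal(wavelength_percentage(28, 646), 4.33)
  expect_equal(wavelength_percentage(33, 646), 5.11)
  expect_equal(wavelength_percentage(0, 646), 0)
  expect_equal(wavelength_percentage(646, 646), 100)
  # self-consistent printed (count, percent) pairs from the study's tables
  pairs <- rbind(c(28, 4.33), c(30, 4.64), c(11, 1.70), c(47, 7.28),
                 c(31, 4.80), c(10, 1.55), c(41, 6.35), c(34, 5.26),
                 c(55, 8.51), c(9, 1.39), c(33, 5.11), c(261, 40.40),
                 c(326, 50.46))
  for (i in seq_len(nrow(pairs)))
    expect_equal(wavelength_percentage(pairs[i, 1], 646), pairs[i, 2])
})

test_that("wavelength_report maps channels to integer nm labels", {
  d <- toy_data(seed = 5, n = 90, p = 50)
  sp <- spxy_split(d$X, d$y, 3)
  res <- run_strategy(d$spectra, d$response, sp, "iRF-CARS-GA",
                      config = small_config(), seed = 1)
  rep_ <- wavelength_report(res)
  expect_equal(rep_$count, length(res$selections$optimal$channels))
  expect_identical(rep_$wavelengths_nm,
                   as.integer(round(d$spectra$grid$centers[rep_$channels])))
  expect_equal(rep_$percent, round(100 * rep_$count / 50, 2))
  empty <- selection_result(integer(0), "optimal", "GA")
  expect_equal(wavelength_report(empty, n_window = 646)$percent, 0)
})

test_that("selection results serialize to JSON and back", {
  parent <- selection_result(1:20, "coarse", "iRF", seed = 1)
  sel <- selection_result(c(3L, 7L, 11L), "fine", "CARS", seed = 1,
                          parent = parent, best_rmsecv = 0.123)
  path <- file.path(tempdir(), "sel.json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_identical(back$channels, sel$channels)
  expect_identical(back$algorithm, "CARS")
  expect_equal(back$best_rmsecv, 0.123)
  expect_error(selection_result(c(2L, 99L), "fine", "CARS", parent = parent),
               "outside its parent")
})
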