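test_that("pixel-wise prediction equals the tabular prediction to 1e-10", {
  d <- toy_data(seed = 1, n = 40, p = 50)
  prep <- default_preprocess()
  pre <- apply_pipeline(d$spectra, prep)
  k <- cv_select_components(pre$reflectance, d$y, 5, seed = 1)$best_k
  model <- fit_plsr(pre$reflectance[, 10:40], d$y, min(k, 5), channels = 10:40)
  tab_pred <- predict(model, pre$reflectance[, 10:40])

  # cube whose first row of pixels carries the raw sample spectra
  H <- 8; W <- 8; p <- 50
  vals <- array(0.02, dim = c(H, W, p))
  for (j in 1:8) vals[1, j, ] <- d$X[j, ]
  cube <- hypercube(vals, d$spectra$grid, calibrated = TRUE)
  mask <- matrix(FALSE, H, W); mask[1, ] <- TRUE
  cmap <- predict_pixelwise(cube, leaf_mask(mask), model, prep = prep)
  for (j in 1:8)
    expect_equal(cmap$values[1, j], tab_pred[j], tolerance = 1e-10)
  expect_true(all(is.na(cmap$values[-1, ])))
})

test_that("empty masks give all-sentinel maps and channel mismatches are named", {
  d <- toy_data(seed = 2, n = 10, p = 30)
  model <- fit_plsr(d$X[, 1:20], d$y, 2, channels = 1:20)
  cube <- hypercube(array(0.5, dim = c(8, 8, 30)), d$spectra$grid,
                    calibrated = TRUE)
  cmap <- predict_pixelwise(cube, leaf_mask(matrix(FALSE, 8, 8)), model)
  expect_true(all(is.na(cmap$values)))

  small <- hypercube(array(0.5, dim = c(8, 8, 10)),
                     wavelength_grid(d$spectra$grid$centers[1:10]),
                     calibrated = TRUE)
  expect_error(predict_pixelwise(small, leaf_mask(matrix(TRUE, 8, 8)), model),
               "lacks model channels")
})

test_that("pixel-wise inversion recovers a smooth planted field (rank r > 0.9)", {
  cfg <- toy_config(seed = 3, p = 60, noise_sd = 0.002)
  sim <- simulate_spectra(cfg)
  prep <- default_preprocess()
  pre <- apply_pipeline(sim$spectra, prep)
  k <- cv_select_components(pre$reflectance, sim$response$values, 6, seed = 1)$best_k
  model <- fit_plsr(pre$reflectance, sim$response$values, k)

  out <- simulate_cube(cfg, shape = c(28, 24))
  cmap <- predict_pixelwise(out$cube, out$truth$mask, model, prep = prep,
                            range = out$truth$range)
  idx <- which(out$truth$mask)
  rho <- cor(cmap$values[idx], out$truth$values[idx], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("the enhanced Lee filter honors its three branches", {
  m <- matrix(TRUE, 9, 9)
  const <- concentration_map(matrix(4, 9, 9), m, range = c(0, 8))
  expect_equal(lee_enhanced(const)$values, const$values, tolerance = 1e-12)

  # heterogeneous: an extreme isolated spike with local C >= heterog survives
  v <- matrix(0.01, 9, 9); v[5, 5] <- 100
  spike <- concentration_map(v, m, range = c(0, 100))
  expect_equal(lee_enhanced(spike)$values[5, 5], 100)

  # homogeneous noisy patch: each pixel becomes its masked 3x3 window mean
  set.seed(4)
  v2 <- matrix(1 + rnorm(81, 0, 0.01), 9, 9)
  noisy <- concentration_map(v2, m, range = c(0, 2))
  filt <- lee_enhanced(noisy)
  for (i in c(2, 5, 8)) for (j in c(3, 6)) {
    win <- v2[(i - 1):(i + 1), (j - 1):(j + 1)]
    expect_equal(filt$values[i, j], mean(win), tolerance = 1e-12)
  }
})

test_that("Lee filtering respects masks and local window bounds", {
  set.seed(5)
  m <- matrix(FALSE, 10, 10); m[3:8, 3:8] <- TRUE
  v <- matrix(NA_real_, 10, 10)
  v[m] <- runif(36, 0, 5)
  cmap <- concentration_map(v, m, range = c(0, 5))
  filt <- lee_enhanced(cmap, size = 3)
  expect_true(all(is.na(filt$values[!m])))
  for (i in 3:8) for (j in 3:8) {
    ri <- max(1, i - 1):min(10, i + 1); rj <- max(1, j - 1):min(10, j + 1)
    win <- v[ri, rj][m[ri, rj]]
    expect_gte(filt$values[i, j], min(win) - 1e-12)
    expect_lte(filt$values[i, j], max(win) + 1e-12)
  }
  expect_error(lee_enhanced(cmap, size = 4), "odd")
})

test_that("pseudocolor rendering hits pure blue and red endpoints monotonically", {
  m <- matrix(TRUE, 1, 5)
  vals <- matrix(c(0, 2, 3.8, 5.5, 7.64), 1, 5)
  cmap <- concentration_map(vals, m, range = c(0, 7.64))
  img <- render_pseudocolor(cmap, colorbar = FALSE)
  expect_equal(as.numeric(img[1, 1, ]), c(0, 0, 1))   # blue at lo
  expect_equal(as.numeric(img[1, 5, ]), c(1, 0, 0))   # red at hi
  # hue position along the blue-to-red ramp is strictly increasing in value
  ramp <- grDevices::colorRamp(c("blue", "#66CCFF", "green", "yellow",
                                 "orange", "red"))
  lut <- ramp(seq(0, 1, length.out = 512)) / 255
  pos <- vapply(1:5, function(j) {
    which.min(colSums((t(lut) - img[1, j, ])^2))
  }, 0L)
  expect_true(all(diff(pos) > 0))

  # identical inputs render identical pixels
  img2 <- render_pseudocolor(cmap, colorbar = FALSE)
  expect_identical(img, img2)

  # all-sentinel map renders uniform neutral grey
  none <- concentration_map(matrix(NA_real_, 4, 4), matrix(FALSE, 4, 4),
                            range = c(0, 1))
  flat <- render_pseudocolor(none, colorbar = FALSE)
  expect_true(all(flat == 0.5))
  bad <- none; bad$range <- c(1, 1)
  expect_error(render_pseudocolor(bad), "lo < hi")
})

test_that("maps render background neutral and write to PNG/TIFF", {
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  v <- matrix(NA_real_, 6, 6); v[m] <- seq(0, 7, length.out = 16)
  cmap <- concentration_map(v, m, range = c(0, 7.64))
  img <- render_pseudocolor(cmap)
  expect_equal(as.numeric(img[1, 1, ]), c(0.5, 0.5, 0.5))
  expect_equal(attr(img, "range"), c(0, 7.64))
  p1 <- file.path(tempdir(), "map.png")
  write_map_png(img, p1)
  expect_true(file.exists(p1))
  p2 <- file.path(tempdir(), "map.tif")
  write_map_tiff(cmap, p2)
  back <- tiff::readTIFF(p2)
  want <- pmin(pmax(v / 7.64, 0), 1)
  want[is.na(want)] <- 0
  expect_equal(back, want, tolerance = 1e-6)
})
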