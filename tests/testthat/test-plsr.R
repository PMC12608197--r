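# Pure-R PLS1 (NIPALS) oracle; for univariate y its predictions coincide
# with SIMPLS at every component count.
nipals_pls1_coef <- function(X, y, k) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- NULL; q <- numeric(0)
  for (a in seq_len(k)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    q_ <- sum(f * t_) / sum(t_^2)
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q_
    W <- cbind(W, w); P <- cbind(P, p_); q <- c(q, q_)
  }
  beta <- W %*% solve(t(P) %*% W, q)
  list(beta = drop(beta), intercept = ym - sum(xm * beta))
}

test_that("PLSR reproduces an exactly linear response at full rank", {
  d <- latent_data(seed = 1, n = 40, p = 10, k = 3)
  m <- fit_plsr(d$X, d$y, 3)
  expect_lt(max(abs(predict(m, d$X) - d$y)), 1e-8)
})

test_that("full-rank PLSR equals ordinary least squares (normal equations oracle)", {
  set.seed(2)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  m <- fit_plsr(X, y, p)
  Xc <- cbind(1, X)
  beta_ols <- solve(t(Xc) %*% Xc, t(Xc) %*% y)
  expect_equal(predict(m, X), as.numeric(Xc %*% beta_ols), tolerance = 1e-8)
})

test_that("PLSR coefficients match a pure-R NIPALS oracle at every k", {
  set.seed(3)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(50, 0, 0.3)
  for (k in c(1, 2, 4)) {
    m <- fit_plsr(X, y, k)
    o <- nipals_pls1_coef(X, y, k)
    expect_equal(m$coefficients, o$beta, tolerance = 1e-8)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-8)
  }
})

test_that("single-column PLSR reduces to univariate regression", {
  set.seed(4)
  x <- rnorm(25)
  y <- 2.5 * x + 1 + rnorm(25, 0, 0.1)
  m <- fit_plsr(matrix(x), y, 1)
  uni <- lm(y ~ x)
  expect_equal(m$coefficients, unname(coef(uni)[2]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(coef(uni)[1]), tolerance = 1e-10)
})

test_that("fit_plsr is deterministic and validates its inputs", {
  d <- latent_data(seed = 5, n = 30, p = 12, k = 2, noise = 0.1)
  a <- fit_plsr(d$X, d$y, 4)
  b <- fit_plsr(d$X, d$y, 4)
  expect_identical(a$coefficients, b$coefficients)
  expect_error(fit_plsr(d$X, rep(1, 30), 2), "constant")
  expect_error(fit_plsr(d$X, d$y, 30), "ncomp")
})

test_that("cross-validated RMSE matches an independent manual fold loop to 1e-10", {
  d <- latent_data(seed = 6, n = 50, p = 10, k = 3, noise = 0.2)
  fold <- cv_folds(50, 10, seed = 99)
  path <- cfoselect:::rmse_cv_path(d$X, d$y, fold, 5)
  for (k in c(1, 3, 5))
    expect_equal(path[k], manual_cv_rmse(d$X, d$y, fold, k), tolerance = 1e-10)
})

test_that("component selection recovers planted latent dimension and caps at 1", {
  d <- latent_data(seed = 7, n = 80, p = 20, k = 3, noise = 0.01)
  sel <- cv_select_components(d$X, d$y, 8, seed = 1)
  expect_equal(sel$best_k, 3)
  sel1 <- cv_select_components(d$X, d$y, 1, seed = 1)
  expect_equal(sel1$best_k, 1)
  expect_error(cv_select_components(d$X[1:5, ], d$y[1:5], 2, folds = 10),
               "folds")
  # error trace non-increasing up to the true k for the noiseless model
  d0 <- latent_data(seed = 8, n = 80, p = 20, k = 3, noise = 0)
  tr <- cv_select_components(d0$X, d0$y, 3, seed = 2)$rmse_cv
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("fold assignment is a seeded permutation into balanced blocks", {
  f <- cv_folds(23, 10, seed = 3)
  expect_identical(f, cv_folds(23, 10, seed = 3))
  expect_false(identical(f, cv_folds(23, 10, seed = 4)))
  expect_true(all(tabulate(f) %in% c(2, 3)))
  expect_error(cv_folds(5, 10), "folds")
})

test_that("evaluate computes R, RMSE and RPD by their defining formulas", {
  y <- c(1, 2, 3); yhat <- c(1.1, 1.9, 3.2)
  m <- list(coefficients = 1, intercept = 0, channels = 1L)
  class(m) <- "plsr_model"
  rep_ <- evaluate(m, matrix(yhat), y, "prediction")
  expect_equal(rep_$RMSE, sqrt(0.02), tolerance = 1e-12)
  expect_equal(rep_$R, cor(yhat, y), tolerance = 1e-12)
  expect_equal(rep_$RPD, sd(y) / sqrt(0.02), tolerance = 1e-12)

  perfect <- evaluate(m, matrix(y), y)
  expect_equal(perfect$R, 1)
  expect_equal(perfect$RMSE, 0)
  expect_identical(perfect$RPD, Inf)

  m0 <- list(coefficients = 0, intercept = mean(y), channels = 1L)
  class(m0) <- "plsr_model"
  expect_warning(null_rep <- evaluate(m0, matrix(y), y), "constant")
  expect_true(is.na(null_rep$R))
  expect_equal(null_rep$RMSE, sqrt(mean((y - mean(y))^2)), tolerance = 1e-12)
  expect_error(evaluate(m, matrix(1), 1), "at least 2")
})

test_that("PLSR models round-trip through JSON with identical predictions", {
  d <- latent_data(seed = 10, n = 30, p = 6, k = 2, noise = 0.1)
  m <- fit_plsr(d$X, d$y, 3, channels = 11:16)
  path <- file.path(tempdir(), "model.json")
  write_plsr_json(m, path)
  back <- read_plsr_json(path)
  expect_equal(predict(back, d$X), predict(m, d$X), tolerance = 1e-12)
  expect_identical(back$channels, m$channels)
  expect_equal(back$ncomp, m$ncomp)
})

test_that("evaluation is invariant to a consistent channel permutation", {
  d <- latent_data(seed = 9, n = 40, p = 8, k = 2, noise = 0.1)
  m <- fit_plsr(d$X, d$y, 3)
  perm <- sample(8)
  mp <- m
  mp$coefficients <- m$coefficients[perm]
  mp$x_mean <- m$x_mean[perm]
  a <- evaluate(m, d$X, d$y)
  b <- evaluate(mp, d$X[, perm], d$y)
  expect_equal(a$R, b$R, tolerance = 1e-12)
  expect_equal(a$RMSE, b$RMSE, tolerance = 1e-12)
})
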