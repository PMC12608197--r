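#' Exponentially decreasing retention schedule used by CARS
#'
#' Retained-channel counts per Monte Carlo run: `round(p * a * exp(-k * i))`
#' with `a`, `k` fixed by the boundary conditions that run 1 retains all `p`
#' channels and run `n_mc` retains exactly 2.
#'
#' @param p Number of candidate channels.
#' @param n_mc Number of Monte Carlo runs.
#' @return Integer vector of length `n_mc`.
#' @export
cars_edf <- function(p, n_mc) {
  if (n_mc < 2) return(rep(as.integer(p), n_mc))
  a <- (p / 2)^(1 / (n_mc - 1))
  k <- log(p / 2) / (n_mc - 1)
  pmax(2L, pmin(as.integer(p), as.integer(round(p * a * exp(-k * seq_len(n_mc))))))
}

#' Fine selection by competitive adaptive reweighted sampling (CARS)
#'
#' Stage-2 model-population selection. Each of `n_mc` Monte Carlo runs fits
#' a PLSR model on a random `row_fraction` of the calibration rows, ranks
#' the surviving channels by absolute regression coefficient, keeps the
#' number prescribed by the exponentially decreasing function ([cars_edf()]:
#' all channels at run 1, two at run `n_mc`), then applies adaptive
#' reweighted sampling (weighted draws proportional to `|coefficient|`)
#' among the kept channels. Every run's subset is scored by 10-fold RMSE_CV;
#' the subset with the minimal RMSE_CV over all runs is returned (ties:
#' smaller subset, then lowest indices).
#'
#' @inheritParams irf_select
#' @param n_mc Number of Monte Carlo runs.
#' @param row_fraction Fraction of calibration rows fitted per run.
#' @return A [selection_result()] with stage `"fine"`; its trace holds the
#'   per-run subset size and RMSE_CV (the population trace behind the
#'   classic decreasing-then-increasing CARS error curve).
#' @export
cars_select <- function(X, y, n_mc = 100, row_fraction = 0.8,
                        max_components = 10, folds = 10, seed = 1,
                        channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X); n <- nrow(X)
  channels <- as.integer(channels %||% seq_len(p))
  keep_n <- cars_edf(p, n_mc)

  res <- with_seed(seed, {
    fold <- cv_folds(n, folds, seed)
    survivors <- seq_len(p)
    trace <- data.frame(run = seq_len(n_mc), n_channels = NA_integer_,
                        rmse_cv = NA_real_)
    best <- list(cols = survivors, err = Inf)
    for (i in seq_len(n_mc)) {
      rows <- sample.int(n, max(2L, round(row_fraction * n)))
      ksub <- min(max_components, length(rows) - 1L, length(survivors))
      fit <- .simpls_path(X[rows, survivors, drop = FALSE], y[rows], ksub)
      b <- abs(fit$B[, ksub])
      nk <- min(keep_n[i], length(survivors))
      kept <- survivors[order(b, decreasing = TRUE)[seq_len(nk)]]
      wts <- b[match(kept, survivors)]
      if (nk > 2 && sum(wts) > 0) {   # adaptive reweighted sampling
        draw <- sample(kept, size = nk, replace = TRUE, prob = wts)
        kept <- sort(unique(draw))
        if (length(kept) < 2L) kept <- survivors[order(b, decreasing = TRUE)[1:2]]
      }
      survivors <- sort(kept)
      err <- rmsecv(X, y, survivors, fold, max_components)
      trace$n_channels[i] <- length(survivors); trace$rmse_cv[i] <- err
      if (err < best$err ||
          (err == best$err && length(survivors) < length(best$cols)))
        best <- list(cols = survivors, err = err)
    }
    list(best = best, trace = trace)
  })
  selection_result(to_window(res$best$cols, channels), "fine", "CARS",
                   trace = res$trace, seed = seed, best_rmsecv = res$best$err)
}

#' Fine selection by bootstrapping soft shrinkage (BOSS)
#'
#' Stage-2 selection by weighted bootstrap sampling of channels. Channel
#' weights start uniform; each round draws `submodels_per_round` sub-models
#' by bootstrap sampling channels with probability proportional to their
#' weights, fits PLSR, keeps the best `keep_fraction` by RMSE_CV, and
#' replaces the weights by the accumulated normalized `|coefficient|` mass
#' of the kept models (soft shrinkage: weights shrink smoothly, channels are
#' only lost once their weight underflows to zero). Rounds continue until
#' the number of positive-weight channels stops shrinking, the total budget
#' of `n_bootstrap` sub-models is spent, or fewer than 3 channels remain.
#' The minimal-RMSE_CV subset ever evaluated is returned.
#'
#' @inheritParams irf_select
#' @param n_bootstrap Total sub-model budget.
#' @param submodels_per_round Sub-models per weight update.
#' @param keep_fraction Elite fraction of sub-models kept per round.
#' @return A [selection_result()] with stage `"fine"`; `$weights` holds the
#'   final weight vector (summing to 1) over the input channels.
#' @export
boss_select <- function(X, y, n_bootstrap = 1000, submodels_per_round = 100,
                        keep_fraction = 0.10, max_components = 10,
                        folds = 10, seed = 1, channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X); n <- nrow(X)
  channels <- as.integer(channels %||% seq_len(p))
  n_rounds <- max(1L, ceiling(n_bootstrap / submodels_per_round))

  res <- with_seed(seed, {
    fold <- cv_folds(n, folds, seed)
    w <- rep(1 / p, p)
    best <- list(cols = seq_len(p), err = Inf)
    trace <- data.frame(round = integer(0), n_active = integer(0),
                        best_rmse_cv = numeric(0))
    n_active_prev <- p
    for (r in seq_len(n_rounds)) {
      elite_err <- numeric(0); elite_mass <- matrix(0, 0, p)
      errs <- numeric(submodels_per_round)
      masses <- vector("list", submodels_per_round)
      for (m in seq_len(submodels_per_round)) {
        draw <- sample.int(p, size = p, replace = TRUE, prob = w)
        inc <- sort(unique(draw))
        if (length(inc) < 2L)
          inc <- sort(unique(c(inc, sample.int(p, 2L, prob = pmax(w, 1e-12)))))
        ksub <- min(max_components, n - 1L, length(inc))
        fit <- .simpls_path(X[, inc, drop = FALSE], y, ksub)
        beta <- abs(fit$B[, ksub])
        mass <- numeric(p)
        if (sum(beta) > 0) mass[inc] <- beta / sum(beta)
        masses[[m]] <- mass
        errs[m] <- rmsecv(X, y, inc, fold, max_components)
        if (errs[m] < best$err ||
            (errs[m] == best$err && length(inc) < length(best$cols)))
          best <- list(cols = inc, err = errs[m])
      }
      elite <- order(errs)[seq_len(max(1L, ceiling(keep_fraction * submodels_per_round)))]
      acc <- Reduce(`+`, masses[elite])
      if (sum(acc) > 0) w <- acc / sum(acc)
      trace <- rbind(trace, data.frame(round = r, n_active = sum(w > 0),
                                       best_rmse_cv = min(errs)))
      n_active <- sum(w > 0)
      if (n_active >= n_active_prev && r > 1) break
      if (n_active < 3L) break
      n_active_prev <- n_active
    }
    list(best = best, w = w, trace = trace)
  })
  out <- selection_result(to_window(res$best$cols, channels), "fine", "BOSS",
                          trace = res$trace, seed = seed,
                          best_rmsecv = res$best$err)
  out$weights <- res$w
  out
}

#' Fine selection by variable combination population analysis (VCPA)
#'
#' Stage-2 selection combining binary-matrix sampling with an exponentially
#' decreasing candidate pool. For `n_edf_iters` iterations, `n_bms` random
#' binary variable combinations (each pooled channel included with
#' probability `inclusion_ratio`) are fitted by PLSR and scored by RMSE_CV;
#' the best `keep_fraction` define per-channel inclusion frequencies, and
#' the pool shrinks along a geometric schedule from `p` down to `final_pool`
#' channels at the last iteration, keeping the highest-frequency channels.
#' The surviving pool is then searched directly: nested top-frequency
#' subsets (and, for pools of at most 12 channels, all pairs and triples)
#' are evaluated exhaustively and the minimal-RMSE_CV subset returned.
#' `n_edf_iters = 0` returns the initial pool unchanged.
#'
#' @inheritParams irf_select
#' @param n_bms Binary combinations sampled per iteration.
#' @param n_edf_iters Pool-shrinkage iterations.
#' @param keep_fraction Elite fraction defining inclusion frequencies.
#' @param final_pool Pool size after the last shrinkage iteration.
#' @param inclusion_ratio Inclusion probability per channel per combination.
#' @return A [selection_result()] with stage `"fine"`.
#' @export
vcpa_select <- function(X, y, n_bms = 1000, n_edf_iters = 50,
                        keep_fraction = 0.10, final_pool = 100,
                        inclusion_ratio = 0.1, max_components = 10,
                        folds = 10, seed = 1, channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X); n <- nrow(X)
  channels <- as.integer(channels %||% seq_len(p))

  if (n_edf_iters == 0)
    return(selection_result(to_window(seq_len(p), channels), "fine", "VCPA",
                            seed = seed))

  sched <- vcpa_pool_schedule(p, final_pool, n_edf_iters)
  res <- with_seed(seed, {
    fold <- cv_folds(n, folds, seed)
    pool <- seq_len(p)
    best <- list(cols = pool, err = Inf)
    trace <- data.frame(iteration = seq_len(n_edf_iters),
                        pool_size = NA_integer_, best_rmse_cv = NA_real_)
    freq <- rep(1, p)
    for (i in seq_len(n_edf_iters)) {
      errs <- numeric(n_bms); subs <- vector("list", n_bms)
      for (m in seq_len(n_bms)) {
        inc <- pool[runif(length(pool)) < inclusion_ratio]
        if (length(inc) < 2L)
          inc <- sort(unique(c(inc, sample(pool, min(2L, length(pool))))))
        subs[[m]] <- inc
        errs[m] <- rmsecv(X, y, inc, fold, max_components)
        if (errs[m] < best$err ||
            (errs[m] == best$err && length(inc) < length(best$cols)))
          best <- list(cols = inc, err = errs[m])
      }
      elite <- order(errs)[seq_len(max(1L, ceiling(keep_fraction * n_bms)))]
      freq <- numeric(p)
      for (m in elite) freq[subs[[m]]] <- freq[subs[[m]]] + 1
      keep_sz <- min(sched[i], length(pool))
      pool <- pool[order(freq[pool], decreasing = TRUE)[seq_len(keep_sz)]]
      pool <- sort(pool)
      trace$pool_size[i] <- length(pool); trace$best_rmse_cv[i] <- min(errs)
    }
    # direct search of the surviving pool
    ranked <- pool[order(freq[pool], decreasing = TRUE)]
    cand <- lapply(2:min(length(ranked), 30L), function(m) sort(ranked[seq_len(m)]))
    if (length(pool) <= 12L) {
      prs <- utils::combn(pool, 2L, simplify = FALSE)
      trp <- if (length(pool) >= 3L) utils::combn(pool, 3L, simplify = FALSE) else list()
      cand <- c(cand, prs, trp)
    }
    for (cc in cand) {
      e <- rmsecv(X, y, cc, fold, max_components)
      if (e < best$err || (e == best$err && length(cc) < length(best$cols)))
        best <- list(cols = cc, err = e)
    }
    list(best = best, trace = trace)
  })
  selection_result(to_window(res$best$cols, channels), "fine", "VCPA",
                   trace = res$trace, seed = seed, best_rmsecv = res$best$err)
}

#' @rdname vcpa_select
#' @param p Number of candidate channels.
#' @export
vcpa_pool_schedule <- function(p, final_pool = 100, n_edf_iters = 50) {
  if (p <= final_pool) return(rep(as.integer(p), n_edf_iters))
  sizes <- round(p * (final_pool / p)^(seq_len(n_edf_iters) / n_edf_iters))
  as.integer(pmin(p, pmax(final_pool, cummin(sizes))))
}
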