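#' Coarse interval selection by interval random frog ("iRF")
#'
#' Stage-1 coarse selection over contiguous wavelength intervals. The search
#' state is a set of moving windows of fixed width; starting from
#' `n_subintervals` equidistant windows, each iteration proposes adding,
#' removing, or shifting one window, scores the union of covered channels by
#' PLSR RMSE_CV (10-fold, latent variables capped at `max_components`), and
#' accepts the proposal when the error improves within an annealed tolerance
#' (5% of the current error at the start, 0 at the end). Per-channel
#' selection frequencies are accumulated over the visited states; channels
#' above `freq_threshold` are returned (`freq_threshold = 0` returns every
#' channel). With `n_iterations = 0` the initial equidistant interval set is
#' returned unchanged.
#'
#' @param X Calibration spectra ([spectra_table()] or matrix).
#' @param y Calibration responses.
#' @param n_iterations Number of reversible-jump iterations.
#' @param window_width Interval width in channels.
#' @param n_subintervals Number of equidistant starting intervals.
#' @param max_components Latent-variable cap for the PLSR sub-models.
#' @param freq_threshold Selection-frequency cutoff (fraction of visited
#'   states).
#' @param folds CV folds.
#' @param seed Integer seed; identical seeds reproduce identical selections.
#' @param channels Window coordinates of the columns of `X`.
#' @return A [selection_result()] with stage `"coarse"`.
#' @export
irf_select <- function(X, y, n_iterations = 1000, window_width = 10,
                       n_subintervals = 20, max_components = 10,
                       freq_threshold = 0.5, folds = 10, seed = 1,
                       channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X)
  if (p < window_width) stopf("need at least window_width = %d channels", window_width)
  channels <- as.integer(channels %||% seq_len(p))
  n_starts <- p - window_width + 1L
  cover <- function(starts)
    sort(unique(unlist(lapply(starts, function(s) s:(s + window_width - 1L)))))
  init <- unique(round(seq(1, n_starts, length.out = min(n_subintervals, n_starts))))

  if (n_iterations == 0) {
    return(selection_result(to_window(cover(init), channels), "coarse", "iRF",
                            seed = seed))
  }

  res <- with_seed(seed, {
    fold <- cv_folds(nrow(X), folds, seed)
    state <- init
    err <- rmsecv(X, y, cover(state), fold, max_components)
    freq <- numeric(p)
    trace <- data.frame(iteration = seq_len(n_iterations),
                        n_channels = NA_integer_, rmse_cv = NA_real_)
    best <- list(cols = cover(state), err = err)
    for (i in seq_len(n_iterations)) {
      prop <- state
      # removal-leaning proposal mix: additions must earn their keep
      move <- sample(3L, 1L, prob = c(0.2, 0.45, 0.35))
      if (move == 1L) {                       # add
        free <- setdiff(seq_len(n_starts), prop)
        if (length(free) > 0) prop <- c(prop, free[sample.int(length(free), 1L)])
      } else if (move == 2L && length(prop) > 1L) {   # remove
        prop <- prop[-sample.int(length(prop), 1L)]
      } else {                                # shift one interval
        j <- sample.int(length(prop), 1L)
        shifted <- prop[j] + sample(c(-3:-1, 1:3), 1L)
        if (shifted >= 1 && shifted <= n_starts && !(shifted %in% prop[-j]))
          prop[j] <- shifted
      }
      if (!identical(sort(prop), sort(state))) {
        e2 <- rmsecv(X, y, cover(prop), fold, max_components)
        tol <- 0.05 * (1 - i / n_iterations)
        # parsimony-biased acceptance: growing the model must strictly improve
        # the error; shrinking it may trade a small (annealed) error increase
        shrinks <- length(cover(prop)) < length(cover(state))
        if (e2 < err || (shrinks && e2 < err * (1 + tol))) {
          state <- prop; err <- e2
        }
        if (e2 < best$err) best <- list(cols = cover(prop), err = e2)
      }
      cols <- cover(state)
      # burn-in: frequencies are tallied once the early all-interval states
      # have had a chance to be pruned away
      if (i > n_iterations / 2) freq[cols] <- freq[cols] + 1
      trace$n_channels[i] <- length(cols); trace$rmse_cv[i] <- err
    }
    freq <- freq / max(1, n_iterations - floor(n_iterations / 2))
    sel <- if (freq_threshold <= 0) seq_len(p) else which(freq > freq_threshold)
    if (length(sel) == 0) sel <- best$cols  # fall back to the best visited state
    list(sel = sel, trace = trace,
         err = rmsecv(X, y, sel, fold, max_components))
  })
  selection_result(to_window(res$sel, channels), "coarse", "iRF",
                   trace = res$trace, seed = seed, best_rmsecv = res$err)
}

#' Coarse selection by interval variable iterative space shrinkage (iVISSA)
#'
#' Stage-1 coarse selection by weighted bootstrap Monte Carlo sampling.
#' Every channel starts with inclusion weight `w0`; each round draws
#' `n_submodels` sub-models by weighted inclusion sampling, scores them by
#' PLSR RMSE_CV, and moves the weights to each channel's frequency among the
#' best `best_fraction` of sub-models (soft space shrinkage). Rounds stop
#' when the weights converge (`max |dw| < tol`) or after `n_rounds`.
#' Channels with final weight above 0.5 are kept, and each contiguous run of
#' kept channels is grown outward while adding the neighbouring channel
#' lowers RMSE_CV. With `shrink = FALSE` the weights are never updated, so
#' `w0 = 1` selects the full channel set.
#'
#' @inheritParams irf_select
#' @param n_submodels Sub-models drawn per round.
#' @param w0 Initial inclusion weight per channel.
#' @param best_fraction Fraction of sub-models treated as elite.
#' @param tol Convergence tolerance on the weight update.
#' @param n_rounds Round cap.
#' @param shrink Update weights between rounds?
#' @return A [selection_result()] with stage `"coarse"`; its trace records
#'   per-round best RMSE_CV and the weight vector path.
#' @export
ivissa_select <- function(X, y, n_submodels = 1000, w0 = 0.5,
                          max_components = 10, best_fraction = 0.1,
                          tol = 0.01, n_rounds = 10, shrink = TRUE,
                          folds = 10, seed = 1, channels = NULL) {
  X <- as_X(X); y <- as_y(y)
  check_selector_input(X, y, min_p = 2L)
  p <- ncol(X)
  channels <- as.integer(channels %||% seq_len(p))

  res <- with_seed(seed, {
    fold <- cv_folds(nrow(X), folds, seed)
    w <- rep(w0, p)
    weight_path <- list()
    best_trace <- numeric(0)
    for (r in seq_len(n_rounds)) {
      # fresh folds each round: a null channel that happens to fit one fold
      # split cannot stay lucky across rounds
      fold_r <- cv_folds(nrow(X), folds, seed + r)
      subs <- vector("list", n_submodels)
      errs <- numeric(n_submodels)
      for (m in seq_len(n_submodels)) {
        inc <- which(runif(p) < w)
        if (length(inc) < 2L)
          inc <- unique(c(inc, sample.int(p, 2L, prob = pmax(w, 1e-9))))
        subs[[m]] <- inc
        errs[m] <- rmsecv(X, y, inc, fold_r, max_components)
      }
      elite <- order(errs)[seq_len(max(1L, ceiling(best_fraction * n_submodels)))]
      best_trace <- c(best_trace, min(errs))
      f <- numeric(p)
      for (m in elite) f[subs[[m]]] <- f[subs[[m]]] + 1
      f <- f / length(elite)
      weight_path[[r]] <- w
      if (!shrink) next
      delta <- max(abs(f - w))
      w <- f
      if (delta < tol) break
    }
    if (!shrink) {
      sel <- which(w > 0.5)
      if (length(sel) == 0) sel <- order(w, decreasing = TRUE)[1:2]
      err <- rmsecv(X, y, sel, fold, max_components)
    } else {
      # final space selection: the weight ranking proposes nested candidate
      # subsets; the best by RMSE_CV is grown into contiguous intervals and
      # backward-pruned
      ord <- order(w, decreasing = TRUE)
      sel <- ord[1:2]; err <- Inf
      for (m in unique(c(2L, round(seq(2, p, length.out = 20L))))) {
        cand <- sort(ord[seq_len(m)])
        e2 <- rmsecv(X, y, cand, fold, max_components)
        if (e2 < err) { sel <- cand; err <- e2 }
      }
      for (pass in 1:5) {               # bounded interval growth
        cand <- setdiff(unique(c(sel - 1L, sel + 1L)), sel)
        cand <- cand[cand >= 1 & cand <= p]
        improved <- FALSE
        for (ch in cand) {
          e2 <- rmsecv(X, y, sort(c(sel, ch)), fold, max_components)
          if (e2 < err) { sel <- sort(c(sel, ch)); err <- e2; improved <- TRUE }
        }
        if (!improved) break
      }
      for (pass in 1:3) {               # bounded backward pruning
        improved <- FALSE
        for (ch in sel) {
          if (length(sel) <= 2L) break
          e2 <- rmsecv(X, y, setdiff(sel, ch), fold, max_components)
          if (e2 < err) { sel <- setdiff(sel, ch); err <- e2; improved <- TRUE }
        }
        if (!improved) break
      }
      sel <- sort(sel)
    }
    list(sel = sel, w = w, best_trace = best_trace, err = err,
         weight_path = weight_path)
  })
  trace <- data.frame(round = seq_along(res$best_trace),
                      best_rmse_cv = res$best_trace)
  out <- selection_result(to_window(res$sel, channels), "coarse", "iVISSA",
                          trace = trace, seed = seed, best_rmsecv = res$err)
  out$weights <- res$w
  out
}
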