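#' The twelve coarse-fine-optimal strategies
#'
#' @return Data frame with columns `coarse`, `fine`, `optimal`, `name`:
#'   the cross of \{iRF, iVISSA\} x \{CARS, BOSS, VCPA\} x \{IRIV, GA\}.
#' @export
strategy_grid <- function() {
  g <- expand.grid(optimal = c("IRIV", "GA"),
                   fine = c("CARS", "BOSS", "VCPA"),
                   coarse = c("iRF", "iVISSA"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("coarse", "fine", "optimal")]
  g <- g[order(match(g$coarse, c("iRF", "iVISSA")),
               match(g$fine, c("CARS", "BOSS", "VCPA")),
               match(g$optimal, c("IRIV", "GA"))), ]
  g$name <- paste(g$coarse, g$fine, g$optimal, sep = "-")
  rownames(g) <- NULL
  g
}

#' Cascade configuration
#'
#' Per-algorithm parameter lists passed to the selectors by [run_strategy()].
#' Defaults are the full-scale settings (1000 iRF iterations, 1000 iVISSA /
#' BOSS / VCPA sub-models, 100 CARS runs, 200 GA evaluations, latent
#' variables capped at 10, 10-fold CV); any entry may be overridden, e.g.
#' `cascade_config(irf = list(n_iterations = 100))` for a reduced budget.
#'
#' @param irf,ivissa,cars,boss,vcpa,iriv,ga Named lists of overrides for the
#'   corresponding selector's arguments.
#' @param max_components Global latent-variable cap.
#' @param folds CV folds used everywhere.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(irf = list(), ivissa = list(), cars = list(),
                           boss = list(), vcpa = list(), iriv = list(),
                           ga = list(), max_components = 10, folds = 10) {
  structure(list(irf = irf, ivissa = ivissa, cars = cars, boss = boss,
                 vcpa = vcpa, iriv = iriv, ga = ga,
                 max_components = max_components, folds = folds),
            class = "cascade_config")
}

run_selector <- function(algo, X, y, cfg, seed, channels, parent = NULL) {
  common <- list(X = X[, channels, drop = FALSE], y = y,
                 max_components = cfg$max_components, folds = cfg$folds,
                 seed = seed, channels = channels)
  args <- switch(algo,
                 iRF = c(common, cfg$irf),
                 iVISSA = c(common, cfg$ivissa),
                 CARS = c(common, cfg$cars),
                 BOSS = c(common, cfg$boss),
                 VCPA = c(common, cfg$vcpa),
                 IRIV = c(common, cfg$iriv),
                 GA = c(common, cfg$ga),
                 stopf("unknown selection algorithm '%s'", algo))
  fn <- switch(algo, iRF = irf_select, iVISSA = ivissa_select,
               CARS = cars_select, BOSS = boss_select, VCPA = vcpa_select,
               IRIV = iriv_select, GA = ga_select)
  out <- do.call(fn, args)
  if (algo == "IRIV") out <- out$result
  out$parent <- parent
  if (!is.null(parent) && !all(out$channels %in% parent$channels))
    stopf("stage result escaped its parent subset")   # chain containment
  out
}

stage_metrics <- function(X, y, split, sel_channels, cfg, seed, stage, algo) {
  Xc <- X[split$calibration, sel_channels, drop = FALSE]
  yc <- y[split$calibration]
  k <- cv_select_components(Xc, yc,
                            min(cfg$max_components, length(sel_channels)),
                            folds = cfg$folds, seed = seed)$best_k
  model <- fit_plsr(Xc, yc, k, channels = sel_channels)
  cal <- evaluate(model, Xc, yc, "calibration")
  prd <- evaluate(model, X[split$prediction, sel_channels, drop = FALSE],
                  y[split$prediction], "prediction")
  list(model = model,
       row = data.frame(stage = stage, algorithm = algo,
                        NV = length(sel_channels),
                        R_C = cal$R, RMSE_C = cal$RMSE, RPD_C = cal$RPD,
                        R_P = prd$R, RMSE_P = prd$RMSE, RPD_P = prd$RPD))
}

#' Run one coarse-fine-optimal strategy end-to-end
#'
#' Applies the three selection stages in sequence on the calibration rows
#' only (prediction rows are touched solely by [evaluate()]), refitting a
#' PLSR model (with per-stage CV choice of the latent-variable count) at the
#' full-window baseline and at each stage boundary.
#'
#' @param X Preprocessed, window-cropped spectra ([spectra_table()] or
#'   matrix).
#' @param y Responses ([response_vector()] or numeric).
#' @param split A [spxy_split()] result.
#' @param strategy Character triple `(coarse, fine, optimal)` or a strategy
#'   name like `"iRF-CARS-IRIV"`.
#' @param config A [cascade_config()].
#' @param seed Integer seed (identical seeds give identical results).
#' @return An object of class `cascade_result`: the strategy name, the
#'   chained [selection_result()]s, per-stage models and a metrics table
#'   with columns `stage`, `algorithm`, `NV`, `R_C`, `RMSE_C`, `RPD_C`,
#'   `R_P`, `RMSE_P`, `RPD_P`.
#' @export
run_strategy <- function(X, y, split, strategy, config = cascade_config(),
                         seed = 1) {
  grid <- if (inherits(X, "spectra_table")) X$grid else NULL
  Xm <- as_X(X); ym <- as_y(y)
  if (length(strategy) == 1L) strategy <- strsplit(strategy, "-")[[1]]
  if (length(strategy) != 3L) stopf("strategy must name coarse, fine and optimal algorithms")
  sg <- strategy_grid()
  if (!(strategy[1] %in% sg$coarse && strategy[2] %in% sg$fine &&
        strategy[3] %in% sg$optimal))
    stopf("unknown strategy '%s'", paste(strategy, collapse = "-"))

  p <- ncol(Xm)
  Xcal <- Xm[split$calibration, , drop = FALSE]
  ycal <- ym[split$calibration]
  window <- selection_result(seq_len(p), "window", "full")

  coarse <- run_selector(strategy[1], Xcal, ycal, config, seed,
                         channels = seq_len(p), parent = window)
  fine <- run_selector(strategy[2], Xcal, ycal, config, seed,
                       channels = coarse$channels, parent = coarse)
  optimal <- run_selector(strategy[3], Xcal, ycal, config, seed,
                          channels = fine$channels, parent = fine)

  stages <- list(full = seq_len(p), coarse = coarse$channels,
                 fine = fine$channels, optimal = optimal$channels)
  algos <- c(full = "full spectrum", coarse = strategy[1],
             fine = strategy[2], optimal = strategy[3])
  fits <- lapply(names(stages), function(s)
    stage_metrics(Xm, ym, split, stages[[s]], config, seed, s, algos[[s]]))
  metrics <- do.call(rbind, lapply(fits, `[[`, "row"))
  models <- lapply(fits, `[[`, "model")
  names(models) <- names(stages)

  structure(list(strategy = paste(strategy, collapse = "-"),
                 selections = list(coarse = coarse, fine = fine,
                                   optimal = optimal),
                 models = models, metrics = metrics, n_window = p,
                 grid = grid, seed = seed),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %s\n", x$strategy))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Run all twelve strategies and assemble the comparison table
#'
#' Coarse selections are computed once per coarse algorithm and fine
#' selections once per coarse-fine pair, then shared across strategies, so
#' the twelve cascades cost two coarse, six fine and twelve optimal runs.
#'
#' @inheritParams run_strategy
#' @return List with `results` (named list of twelve [run_strategy()]
#'   outputs) and `comparison` (one row per strategy and stage, with an
#'   `NV_pct` column = NV / window size as a percentage to two decimals and
#'   a `best` flag marking the optimal-stage row with maximal `R_P`, ties
#'   broken by minimal `RMSE_P`).
#' @export
run_all <- function(X, y, split, config = cascade_config(), seed = 1) {
  grid <- if (inherits(X, "spectra_table")) X$grid else NULL
  Xm <- as_X(X); ym <- as_y(y)
  p <- ncol(Xm)
  Xcal <- Xm[split$calibration, , drop = FALSE]
  ycal <- ym[split$calibration]
  window <- selection_result(seq_len(p), "window", "full")
  sg <- strategy_grid()

  coarse_cache <- list(); fine_cache <- list()
  results <- list()
  for (i in seq_len(nrow(sg))) {
    cs <- sg$coarse[i]; fs <- sg$fine[i]; os <- sg$optimal[i]
    if (is.null(coarse_cache[[cs]]))
      coarse_cache[[cs]] <- run_selector(cs, Xcal, ycal, config, seed,
                                         channels = seq_len(p), parent = window)
    coarse <- coarse_cache[[cs]]
    fkey <- paste(cs, fs, sep = "-")
    if (is.null(fine_cache[[fkey]]))
      fine_cache[[fkey]] <- run_selector(fs, Xcal, ycal, config, seed,
                                         channels = coarse$channels,
                                         parent = coarse)
    fine <- fine_cache[[fkey]]
    optimal <- run_selector(os, Xcal, ycal, config, seed,
                            channels = fine$channels, parent = fine)

    stages <- list(full = seq_len(p), coarse = coarse$channels,
                   fine = fine$channels, optimal = optimal$channels)
    algos <- c(full = "full spectrum", coarse = cs, fine = fs, optimal = os)
    fits <- lapply(names(stages), function(s)
      stage_metrics(Xm, ym, split, stages[[s]], config, seed, s, algos[[s]]))
    metrics <- do.call(rbind, lapply(fits, `[[`, "row"))
    models <- lapply(fits, `[[`, "model"); names(models) <- names(stages)
    results[[sg$name[i]]] <- structure(
      list(strategy = sg$name[i],
           selections = list(coarse = coarse, fine = fine, optimal = optimal),
           models = models, metrics = metrics, n_window = p, grid = grid,
           seed = seed),
      class = "cascade_result")
  }

  comparison <- do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    cbind(strategy = r$strategy, m,
          NV_pct = round(100 * m$NV / p, 2))
  }))
  rownames(comparison) <- NULL
  comparison$best <- FALSE
  opt <- which(comparison$stage == "optimal")
  ord <- opt[order(-comparison$R_P[opt], comparison$RMSE_P[opt])]
  comparison$best[ord[1]] <- TRUE
  list(results = results, comparison = comparison)
}

#' Report selected wavelengths in nm and as a share of the window
#'
#' @param result A [cascade_result()] (its optimal stage is reported) or a
#'   [selection_result()].
#' @param grid The window's [wavelength_grid()]; taken from the cascade
#'   result when available.
#' @param n_window Window channel count for the percentage; defaults to the
#'   cascade's window size (646 on the standard modelling window).
#' @return List with `wavelengths_nm` (nearest-integer nm labels, the
#'   field's printing convention), `channels` (exact indices), `count` and
#'   `percent` (count / window, as a percentage rounded to 2 decimals).
#' @export
wavelength_report <- function(result, grid = NULL, n_window = NULL) {
  if (inherits(result, "cascade_result")) {
    sel <- result$selections$optimal
    grid <- grid %||% result$grid
    n_window <- n_window %||% result$n_window
  } else sel <- result
  if (is.null(n_window)) stopf("window size needed for the percentage")
  nm <- if (!is.null(grid)) as.integer(round(grid$centers[sel$channels]))
        else NULL
  list(wavelengths_nm = nm, channels = sel$channels,
       count = length(sel$channels),
       percent = wavelength_percentage(length(sel$channels), n_window))
}

#' @rdname wavelength_report
#' @param count Number of selected channels.
#' @export
wavelength_percentage <- function(count, n_window = 646) {
  round(100 * count / n_window, 2)
}
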