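#' Result of a wavelength-selection stage
#'
#' Records the selected channel indices (expressed in the coordinates of the
#' modelling window), the stage of the coarse-fine-optimal cascade that
#' produced them, the algorithm's RMSE_CV trace, the seed, and the parent
#' selection the stage refined (chained stages always select subsets of
#' their parent).
#'
#' @param channels Integer channel indices, unique, within the window.
#' @param stage One of `"coarse"`, `"fine"`, `"optimal"` (or `"window"` for
#'   the untouched full window).
#' @param algorithm Algorithm name, e.g. `"iRF"`, `"CARS"`, `"IRIV"`.
#' @param trace Optional data frame of per-iteration diagnostics (subset
#'   size, RMSE_CV, ...).
#' @param seed Seed used by the algorithm.
#' @param parent Optional parent `selection_result`; `channels` must be a
#'   subset of `parent$channels`.
#' @param best_rmsecv RMSE_CV of the returned subset, if the algorithm
#'   evaluated one.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(channels, stage, algorithm, trace = NULL,
                             seed = NULL, parent = NULL, best_rmsecv = NULL) {
  channels <- sort(unique(as.integer(channels)))
  if (!is.null(parent)) {
    if (!inherits(parent, "selection_result"))
      stopf("`parent` must be a selection_result")
    if (!all(channels %in% parent$channels))
      stopf("stage '%s' selected channels outside its parent selection", stage)
  }
  structure(list(channels = channels, stage = stage, algorithm = algorithm,
                 trace = trace, seed = seed, parent = parent,
                 best_rmsecv = best_rmsecv),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s/%s: %d channels%s\n", x$stage,
              x$algorithm, length(x$channels),
              if (!is.null(x$best_rmsecv))
                sprintf(", RMSE_CV %.4g", x$best_rmsecv) else ""))
  invisible(x)
}

#' Serialize / restore a selection result as JSON
#'
#' @param x A [selection_result()] (parent chains are flattened to their
#'   channel sets).
#' @param path JSON file path.
#' @return `write_selection` returns `path` invisibly; `read_selection` the
#'   restored `selection_result` (trace and parent models omitted).
#' @export
write_selection <- function(x, path) {
  chain <- list()
  p <- x$parent
  while (!is.null(p)) {
    chain[[length(chain) + 1L]] <- list(stage = p$stage, algorithm = p$algorithm,
                                        channels = p$channels)
    p <- p$parent
  }
  jsonlite::write_json(list(channels = x$channels, stage = x$stage,
                            algorithm = x$algorithm, seed = x$seed,
                            best_rmsecv = x$best_rmsecv, parents = chain),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_result(obj$channels, obj$stage, obj$algorithm,
                   seed = obj$seed, best_rmsecv = obj$best_rmsecv)
}

# Shared entry validation for the selectors.
check_selector_input <- function(X, y, min_p = 2L) {
  if (nrow(X) != length(y)) stopf("X and y disagree on sample count")
  if (sd(y) == 0) stopf("selection undefined for a constant response")
  if (ncol(X) < min_p) stopf("need at least %d candidate channels", min_p)
  invisible(TRUE)
}

# Map local column positions back to window coordinates.
to_window <- function(local, channels) sort(unique(channels[local]))
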