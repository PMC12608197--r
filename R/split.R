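#' SPXY calibration/prediction partitioning
#'
#' Sample set partitioning using the joint x-y distance: a deterministic
#' Kennard-Stone farthest-point selection on the normalized joint distance
#' `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`, with Euclidean distance in
#' the spectra and absolute difference in the response. The first two
#' calibration samples are the pair at maximal joint distance; each further
#' calibration sample maximizes its minimum distance to the already selected
#' set (ties broken by lowest index). The calibration set receives
#' `floor(n * ratio / (ratio + 1))` samples; the remainder form the
#' prediction set, so a 3:1 split of 735 samples yields 551 and 184.
#'
#' @param X A [spectra_table()] or numeric matrix.
#' @param y A [response_vector()] or numeric vector (non-constant).
#' @param ratio Calibration:prediction ratio, as a number (`3` means 3:1) or
#'   a string `"3:1"`.
#' @return An object of class `dataset_split` with sorted integer fields
#'   `calibration` and `prediction` and the numeric `ratio`.
#' @export
spxy_split <- function(X, y, ratio = 3) {
  X <- as_X(X); y <- as_y(y)
  n <- nrow(X)
  if (length(y) != n) stopf("X and y disagree on sample count")
  if (n < 4) stopf("SPXY needs at least 4 samples")
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":")[[1]])
    ratio <- parts[1] / parts[2]
  }
  dy <- as.matrix(dist(y, method = "manhattan"))
  if (max(dy) == 0) stopf("SPXY undefined for a constant response")
  dx <- as.matrix(dist(X))
  D <- dx / max(dx) + dy / max(dy)

  ncal <- floor(n * ratio / (ratio + 1))
  # farthest pair, lowest indices on ties
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  first <- flat[order(flat[, 1], flat[, 2])[1], ]
  sel <- as.integer(unname(first))
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < ncal) {
    nxt <- which.max(mind)  # which.max returns the first (lowest-index) max
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(calibration = sort(unname(sel)),
                 prediction = setdiff(seq_len(n), sel),
                 ratio = ratio),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d calibration / %d prediction (ratio %.3g:1)\n",
              length(x$calibration), length(x$prediction), x$ratio))
  invisible(x)
}

#' Per-set response summary of a partition
#'
#' @param y A [response_vector()] or numeric vector.
#' @param split A [dataset_split()].
#' @return Data frame with one row per non-empty set and columns `set`, `n`,
#'   `max`, `min`, `mean`, `sd` (sample SD, n-1).
#' @export
dataset_summary <- function(y, split) {
  y <- as_y(y)
  sets <- list(calibration = split$calibration, prediction = split$prediction)
  if (any(vapply(sets, length, 0L) == 0L) && all(vapply(sets, length, 0L) == 0L))
    stopf("split contains no samples")
  rows <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    if (length(idx) == 0L) return(NULL)
    v <- y[idx]
    data.frame(set = nm, n = length(v), max = max(v), min = min(v),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
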