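#' Wavelength grid of a hyperspectral sensor
#'
#' A strictly increasing, uniformly spaced set of band centers in nanometres.
#' The default VNIR grid reproduces a benchtop push-broom imager covering
#' 380-1000 nm at a 0.727 nm sampling interval (856 bands).
#'
#' @param centers Numeric vector of band centers in nm, strictly increasing
#'   and uniformly spaced (within 1e-6 nm).
#' @return An object of class `wavelength_grid` with fields `centers` and
#'   `sampling_interval`.
#' @examples
#' g <- vnir_grid()
#' length(g$centers)     # 856
#' g$sampling_interval   # 0.727
#' @export
wavelength_grid <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 1L) stopf("grid must contain at least one band")
  if (length(centers) > 1L) {
    d <- diff(centers)
    if (any(d <= 0)) stopf("wavelength centers must be strictly increasing")
    if (diff(range(d)) > 1e-6)
      stopf("wavelength spacing must be uniform within 1e-6 nm")
    interval <- mean(d)
  } else {
    interval <- NA_real_
  }
  structure(list(centers = centers, sampling_interval = interval),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @export
vnir_grid <- function() wavelength_grid(380 + 0.727 * (0:855))

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.3f-%.3f nm, interval %.4g nm\n",
              length(x$centers), min(x$centers), max(x$centers),
              x$sampling_interval))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$centers)

# Channel indices retained by a [lo, hi] nm window.
#
# Convention: centers with lo <= lambda <= hi are retained; if the upper cut
# falls strictly inside the grid and the topmost retained center lies within
# half a sampling interval of the cut, that channel is treated as straddling
# the window boundary and dropped (unless it is the only channel left). On
# the 856-band VNIR grid a 430-900 nm window therefore keeps exactly 646
# channels (430.163-899.078 nm), the count that drives all percentage
# bookkeeping downstream.
window_indices <- function(grid, lo, hi) {
  if (lo > hi) stopf("window lower bound exceeds upper bound")
  lam <- grid$centers
  keep <- which(lam >= lo & lam <= hi)
  if (length(keep) == 0L)
    stopf("window [%g, %g] nm retains no channels", lo, hi)
  interval <- grid$sampling_interval
  if (length(keep) > 1L && is.finite(interval) &&
      hi < max(lam) - 1e-9 &&
      (hi - lam[keep[length(keep)]]) < interval / 2) {
    keep <- keep[-length(keep)]
  }
  keep
}
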