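#' Per-pixel analyte concentration map
#'
#' @param values Numeric H x W matrix of analyte estimates; background
#'   pixels carry the sentinel `NA`.
#' @param mask A [leaf_mask()] or logical matrix of the same shape.
#' @param range Display range `(lo, hi)` in analyte units (defaults:
#'   nitrogen 0-7.64 %, chlorophyll 0-3.70 mg/g in the standard workflow);
#'   values are clipped to it for display only.
#' @param units,analyte Units and analyte label.
#' @return An object of class `concentration_map`.
#' @export
concentration_map <- function(values, mask, range = c(0, 7.64),
                              units = "%", analyte = "nitrogen") {
  values <- as.matrix(values)
  mask <- leaf_mask(mask)
  if (!identical(dim(values), dim(unclass(mask))))
    stopf("map and mask shapes differ")
  if (length(range) != 2L || range[1] >= range[2])
    stopf("display range must satisfy lo < hi")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, range = range,
                 units = units, analyte = analyte),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<concentration_map> %s [%s], %d leaf pixels%s\n", x$analyte,
              x$units, sum(x$mask),
              if (length(v)) sprintf(", %.3f-%.3f", min(v), max(v)) else ""))
  invisible(x)
}

#' Pixel-wise inversion of a PLSR model over a cube
#'
#' Applies the model's preprocessing pipeline to every masked pixel's
#' spectrum over the full modelling window, extracts the model's channel
#' subset, and evaluates the regression, so a pixel whose spectrum equals a
#' calibration sample's mean spectrum receives exactly the tabular model
#' prediction. Background pixels carry the sentinel `NA`.
#'
#' @param cube A calibrated [hypercube()] cropped to the model's window.
#' @param mask A [leaf_mask()].
#' @param model A [fit_plsr()] model whose `channels` index the window.
#' @param prep Optional [preprocess_spec()] matching the tabular pipeline.
#' @param range Display range for the resulting map.
#' @param units,analyte Passed to [concentration_map()].
#' @return A [concentration_map()]. Stored values are unclamped; clipping to
#'   the display range happens at rendering time.
#' @export
predict_pixelwise <- function(cube, mask, model, prep = NULL,
                              range = c(0, 7.64), units = "%",
                              analyte = "nitrogen") {
  if (!inherits(cube, "hypercube")) stopf("`cube` must be a hypercube")
  if (!cube$calibrated) stopf("pixel-wise inversion needs a calibrated cube")
  d <- dim(cube$values)
  if (max(model$channels) > d[3]) {
    miss <- model$channels[model$channels > d[3]]
    lam <- if (!is.null(model$wavelengths))
      paste(sprintf("%.0f nm", model$wavelengths[model$channels > d[3]]),
            collapse = ", ")
    else paste("channel", paste(miss, collapse = ", "))
    stopf("cube lacks model channels: %s", lam)
  }
  vals <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask)
  if (length(idx) > 0) {
    flat <- matrix(cube$values, d[1] * d[2], d[3])[idx, , drop = FALSE]
    if (!is.null(prep) && length(prep) > 0)
      flat <- t(apply(flat, 1, apply_steps, spec = prep,
                      wavelengths = cube$grid$centers))
    vals[idx] <- predict(model, flat[, model$channels, drop = FALSE])
  }
  concentration_map(vals, mask, range = range, units = units,
                    analyte = analyte)
}

#' Enhanced Lee speckle filter on a concentration map
#'
#' Classifies each masked pixel's neighbourhood by its coefficient of
#' variation `C = sd/|mean|` (background pixels excluded from every
#' window): homogeneous windows (`C <= homog`) are replaced by the local
#' mean, heterogeneous ones (`C >= heterog`) are preserved exactly, and
#' intermediate pixels take the damped blend `w * mean + (1 - w) * pixel`
#' with `w = exp(-damping * (C - homog) / (heterog - C))`. Output values
#' never leave the local window's `[min, max]` and the mask is preserved.
#'
#' @param map A [concentration_map()].
#' @param size Odd window size >= 3.
#' @param damping Damping coefficient of the blend weight.
#' @param homog,heterog Homogeneity / heterogeneity thresholds on `C`.
#' @return The filtered [concentration_map()].
#' @export
lee_enhanced <- function(map, size = 3, damping = 1, homog = 0.52,
                         heterog = 1.73) {
  if (size < 3 || size %% 2 != 1) stopf("filter size must be odd and >= 3")
  if (!inherits(map, "concentration_map")) stopf("`map` must be a concentration_map")
  v <- map$values; m <- unclass(map$mask)
  H <- nrow(v); W <- ncol(v); h <- (size - 1) / 2
  out <- v
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!m[i, j]) next
    ri <- max(1, i - h):min(H, i + h)
    rj <- max(1, j - h):min(W, j + h)
    win <- v[ri, rj][m[ri, rj]]
    mu <- mean(win)
    cv <- if (length(win) < 2 || mu == 0) 0 else sd(win) / abs(mu)
    out[i, j] <- if (cv <= homog) mu
    else if (cv >= heterog) v[i, j]
    else {
      w <- exp(-damping * (cv - homog) / (heterog - cv))
      w * mu + (1 - w) * v[i, j]
    }
  }
  map$values <- out
  map
}

#' Render a concentration map as a pseudocolor image
#'
#' Monotone blue-to-red colormap over the display range (blue at `lo`
#' through light blue, green, yellow and orange to red at `hi`); values are
#' clipped to the range, background pixels render neutral grey. A vertical
#' colorbar strip (low at the bottom) is appended on the right when
#' `colorbar = TRUE`; the display range and units are attached as
#' attributes.
#'
#' @param map A [concentration_map()].
#' @param colorbar Append the colorbar strip?
#' @return Numeric H x W' x 3 RGB array in \[0, 1\] with attributes `range`
#'   and `units`; write it with [write_map_png()].
#' @export
render_pseudocolor <- function(map, colorbar = TRUE) {
  lo <- map$range[1]; hi <- map$range[2]
  if (lo >= hi) stopf("display range must satisfy lo < hi")
  ramp <- grDevices::colorRamp(c("blue", "#66CCFF", "green", "yellow",
                                 "orange", "red"))
  H <- nrow(map$values); W <- ncol(map$values)
  img <- array(0.5, dim = c(H, W, 3))  # neutral background
  idx <- which(unclass(map$mask))
  if (length(idx) > 0) {
    t_ <- (map$values[idx] - lo) / (hi - lo)
    t_ <- pmin(pmax(t_, 0), 1)
    rgb <- ramp(t_) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- rgb[, ch]
      img[, , ch] <- plane
    }
  }
  if (colorbar) {
    barw <- max(3L, round(W / 16))
    gap <- matrix(1, H, 2)
    tt <- seq(1, 0, length.out = H)
    barcol <- ramp(tt) / 255
    out <- array(1, dim = c(H, W + 2 + barw, 3))
    for (ch in 1:3) {
      out[, seq_len(W), ch] <- img[, , ch]
      out[, W + 2 + seq_len(barw), ch] <- matrix(barcol[, ch], H, barw)
      out[, W + 1:2, ch] <- gap
    }
    img <- out
  }
  attr(img, "range") <- map$range
  attr(img, "units") <- map$units
  img
}

#' Write a rendered map (or any RGB array) to PNG
#'
#' @param img RGB array from [render_pseudocolor()].
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Write a concentration map as a plain float TIFF
#'
#' Values are stored as 32-bit floats normalized by the display range
#' (`(v - lo) / (hi - lo)`, clipped to \[0, 1\] -- the float convention of
#' the TIFF writer); multiply by the range to recover analyte units.
#' Background sentinel pixels are written as 0.
#'
#' @param map A [concentration_map()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  lo <- map$range[1]; hi <- map$range[2]
  v <- pmin(pmax((map$values - lo) / (hi - lo), 0), 1)
  v[is.na(v)] <- 0
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
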