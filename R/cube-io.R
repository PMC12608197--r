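#' Hyperspectral reflectance cube
#'
#' An H x W x B array of reflectance values on a [wavelength_grid()]. Raw
#' (uncalibrated) cubes hold sensor counts; calibrated cubes hold
#' dimensionless reflectance expected to lie in \[-0.05, 1.5\] (tolerant of
#' sensor noise around the physical \[0, 1\] range).
#'
#' @param values Numeric 3-d array, H x W x B.
#' @param grid A [wavelength_grid()] with B centers.
#' @param calibrated Logical flag; set by [radiometric_correct()].
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, grid, calibrated = FALSE) {
  if (length(dim(values)) != 3L) stopf("cube values must be an H x W x B array")
  if (dim(values)[3] != length(grid$centers))
    stopf("cube has %d bands but grid has %d", dim(values)[3],
          length(grid$centers))
  if (calibrated && (min(values) < -0.05 || max(values) > 1.5))
    stopf("calibrated reflectance must lie in [-0.05, 1.5]")
  structure(list(values = values, grid = grid, calibrated = isTRUE(calibrated)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands, %scalibrated\n",
              d[1], d[2], d[3], if (x$calibrated) "" else "not "))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Leaf region-of-interest mask
#'
#' @param values Logical H x W matrix (TRUE = leaf pixel).
#' @return An object of class `leaf_mask` (a logical matrix).
#' @export
leaf_mask <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  structure(values, class = c("leaf_mask", "matrix", "array"))
}

#' Radiometric calibration from white and dark references
#'
#' Converts raw sensor counts to reflectance, element-wise:
#' `R = (R0 - Rb) / (Rw - Rb)` where `R0` is the raw cube, `Rw` the white
#' (Spectralon) reference and `Rb` the dark-current reference.
#'
#' References may be full-frame cubes of the raw shape, or single-line
#' (1 x W x B) acquisitions, which are expanded to full frames by
#' replication; full-frame references captured separately can also be passed
#' pre-averaged over lines.
#'
#' @param raw,white,dark [hypercube()] objects on the same grid.
#' @return A calibrated [hypercube()].
#' @export
radiometric_correct <- function(raw, white, dark) {
  for (x in list(raw, white, dark))
    if (!inherits(x, "hypercube")) stopf("inputs must be hypercubes")
  if (!isTRUE(all.equal(raw$grid$centers, white$grid$centers)) ||
      !isTRUE(all.equal(raw$grid$centers, dark$grid$centers)))
    stopf("raw, white and dark cubes must share one wavelength grid")
  d <- dim(raw$values)
  expand <- function(ref, name) {
    rv <- ref$values
    if (identical(dim(rv), d)) return(rv)
    if (dim(rv)[1] == 1L && dim(rv)[2] == d[2] && dim(rv)[3] == d[3]) {
      out <- array(0, d)
      for (b in seq_len(d[3])) out[, , b] <- matrix(rv[1, , b], d[1], d[2], byrow = TRUE)
      return(out)
    }
    stopf("%s reference shape %s does not match raw cube %s", name,
          paste(dim(rv), collapse = "x"), paste(d, collapse = "x"))
  }
  wv <- expand(white, "white"); dv <- expand(dark, "dark")
  denom <- wv - dv
  bad <- which(denom == 0)
  if (length(bad) > 0) {
    ijb <- arrayInd(bad[1], d)
    stopf("white - dark is zero at pixel (%d, %d), band %d (%.3f nm)",
          ijb[1], ijb[2], ijb[3], raw$grid$centers[ijb[3]])
  }
  out <- (raw$values - dv) / denom
  hypercube(out, raw$grid, calibrated = TRUE)
}

#' Restrict a cube or spectra table to a wavelength window
#'
#' Keeps channels whose centers fall in `[lo_nm, hi_nm]`; a topmost channel
#' lying within half a sampling interval of an interior upper cut is treated
#' as straddling the boundary and dropped (see the package vignette). On the
#' default VNIR grid the 430-900 nm modelling window retains exactly 646
#' channels.
#'
#' @param x A [hypercube()] or [spectra_table()].
#' @param lo_nm,hi_nm Window bounds in nm.
#' @return Object of the same class restricted to the window.
#' @export
crop_window <- function(x, lo_nm, hi_nm) UseMethod("crop_window")

#' @export
crop_window.hypercube <- function(x, lo_nm, hi_nm) {
  keep <- window_indices(x$grid, lo_nm, hi_nm)
  hypercube(x$values[, , keep, drop = FALSE],
            wavelength_grid(x$grid$centers[keep]), calibrated = x$calibrated)
}

#' @export
crop_window.spectra_table <- function(x, lo_nm, hi_nm) {
  keep <- window_indices(x$grid, lo_nm, hi_nm)
  spectra_table(x$reflectance[, keep, drop = FALSE],
                wavelength_grid(x$grid$centers[keep]), x$meta)
}

#' Segment the leaf from the background
#'
#' Thresholds the mean near-infrared reflectance (leaves are bright in the
#' NIR, background dark) and keeps the largest connected component.
#'
#' @param cube A calibrated [hypercube()].
#' @param threshold Reflectance threshold on the NIR mean.
#' @param nir_range Length-2 nm range used for the NIR mean (default
#'   760-800 nm; falls back to the top quartile of the grid if the cube does
#'   not cover it).
#' @return A [leaf_mask()]. All-background cubes yield an empty mask with a
#'   warning.
#' @export
segment_leaf <- function(cube, threshold = 0.1, nir_range = c(760, 800)) {
  if (!inherits(cube, "hypercube")) stopf("`cube` must be a hypercube")
  if (!cube$calibrated) stopf("segment_leaf needs a calibrated cube")
  lam <- cube$grid$centers
  bands <- which(lam >= nir_range[1] & lam <= nir_range[2])
  if (length(bands) == 0)
    bands <- which(lam >= stats::quantile(lam, 0.75))
  nir <- apply(cube$values[, , bands, drop = FALSE], c(1, 2), mean)
  m <- nir > threshold
  if (!any(m)) {
    warning("no pixel exceeds the segmentation threshold; empty mask")
    return(leaf_mask(m))
  }
  if (!all(m)) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    lab <- EBImage::imageData(lab)
    counts <- table(lab[lab > 0])
    keep <- as.integer(names(counts)[which.max(counts)])
    m <- lab == keep
  }
  leaf_mask(m)
}

#' Mean spectrum over a region of interest
#'
#' @param cube A [hypercube()].
#' @param mask A [leaf_mask()] of the cube's spatial shape.
#' @return Numeric per-band mean over masked pixels, named by wavelength.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2]))
    stopf("mask shape does not match cube")
  idx <- which(mask)
  if (length(idx) == 0L) stopf("cannot average an empty mask")
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  out <- colMeans(flat[idx, , drop = FALSE])
  names(out) <- sprintf("%.3f", cube$grid$centers)
  out
}

#' Read and write ENVI cubes
#'
#' Band-interleaved-by-line (BIL) float32 binary with a plain-text `.hdr`
#' carrying dimensions and the wavelength list -- the most portable
#' hyperspectral dialect. `write_envi` produces `<path>.hdr` and
#' `<path>.dat`; `read_envi` accepts the basename or the `.hdr` path.
#'
#' @param cube A [hypercube()].
#' @param path File path without extension (or `.hdr` for `read_envi`).
#' @return `write_envi` returns `path` invisibly; `read_envi` a
#'   [hypercube()].
#' @export
write_envi <- function(cube, path) {
  path <- sub("\\.(hdr|dat)$", "", path)
  d <- dim(cube$values)
  hdr <- c("ENVI",
           "description = {cfoselect hyperspectral cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bil",
           "byte order = 0",
           sprintf("calibrated = %d", as.integer(cube$calibrated)),
           "wavelength units = Nanometers",
           paste0("wavelength = {",
                  paste(sprintf("%.6f", cube$grid$centers), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL order: sample fastest, then band, then line.
  arr <- aperm(cube$values, c(2, 3, 1))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  path <- sub("\\.(hdr|dat)$", "", path)
  hdr <- readLines(paste0(path, ".hdr"), warn = FALSE)
  get_num <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), hdr, value = TRUE)
    if (length(ln) == 0) stopf("ENVI header lacks '%s'", key)
    as.numeric(sub(".*=\\s*", "", ln[1]))
  }
  W <- get_num("samples"); H <- get_num("lines"); B <- get_num("bands")
  interleave <- tolower(sub(".*=\\s*", "", grep("^interleave", hdr, value = TRUE)[1]))
  if (!identical(interleave, "bil"))
    stopf("only BIL interleave is supported (got '%s')", interleave)
  if (get_num("data type") != 4) stopf("only float32 (data type 4) is supported")
  wl_txt <- paste(hdr[seq(grep("^wavelength\\s*=", hdr)[1], length(hdr))],
                  collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_txt), ",")[[1]])
  if (length(wl) != B) stopf("header wavelength count does not match bands")
  calibrated <- any(grepl("^calibrated\\s*=\\s*1", hdr))
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = H * W * B, size = 4, endian = "little")
  arr <- aperm(array(raw, dim = c(W, B, H)), c(3, 1, 2))
  hypercube(arr, wavelength_grid(wl), calibrated = calibrated)
}

#' Write and read a leaf mask as a PNG (0/255)
#'
#' @param mask A [leaf_mask()].
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png` a
#'   [leaf_mask()].
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  leaf_mask(img > 0.5)
}
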