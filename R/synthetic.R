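#' Configuration of the synthetic leaf-spectra generator
#'
#' Describes a population of leaf reflectance spectra whose absorption
#' features are driven by a single analyte (nitrogen or chlorophyll). Each
#' planted band contributes a Gaussian absorption dip whose depth scales
#' linearly with the analyte value:
#' `reflectance = gain * (baseline - sum_b effect_b * response * exp(-(lambda-c_b)^2 / (2 w_b^2))) + noise`,
#' clipped to the physical range \[0, 1\]. The baseline is a fixed leaf-like
#' spectral shape -- dark visible region, green reflectance bump near
#' 550 nm, red edge, bright NIR plateau at `baseline_level` -- and `gain` is
#' a per-sample multiplicative scatter factor (`1 + N(0, scatter_sd)`)
#' emulating surface glossiness and geometry, the artefact SNV
#' preprocessing removes. With `scatter_sd = 0` and a degenerate shape the
#' model reduces to a flat baseline minus analyte-scaled dips plus noise.
#'
#' Defaults emulate the study conditions this package targets: 735 samples
#' (245 per growth stage over 3 stages) on an 856-band VNIR grid with
#' diagnostic absorption centered at the shared nitrogen/chlorophyll bands
#' 479 nm and 689 nm, and nitrogen responses drawn uniformly over the
#' observed 0.7374-7.6357 % range.
#'
#' @param seed Integer seed making the simulation reproducible.
#' @param n_samples Number of samples to draw.
#' @param planted_bands Data frame with columns `center` (nm), `width`
#'   (Gaussian SD, nm) and `effect` (reflectance depression per analyte
#'   unit). Centers must lie within the grid.
#' @param baseline_level NIR-plateau reflectance of the baseline shape
#'   (fraction).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise
#'   (reflectance fraction), must be >= 0.
#' @param scatter_sd Standard deviation of the per-sample multiplicative
#'   scatter gain (0 disables scatter).
#' @param flat_baseline Use a flat baseline at `baseline_level` instead of
#'   the leaf-shaped curve (useful for analytically simple fixtures).
#' @param response_range Length-2 numeric `(min, max)` of the analyte, with
#'   `min < max`; responses are drawn uniformly over it.
#' @param analyte,units Analyte label and units carried into the response.
#' @param grid A [wavelength_grid()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 735L,
                              planted_bands = data.frame(
                                center = c(479, 689),
                                width = 15,
                                effect = 0.01),
                              baseline_level = 0.55,
                              noise_sd = 0.005,
                              scatter_sd = 0.03,
                              flat_baseline = FALSE,
                              response_range = c(0.7374, 7.6357),
                              analyte = "nitrogen",
                              units = "%",
                              grid = vnir_grid()) {
  planted_bands <- as.data.frame(planted_bands)
  if (nrow(planted_bands) > 0) {
    if (!all(c("center", "width", "effect") %in% names(planted_bands)))
      stopf("planted_bands needs columns center, width, effect")
    rng <- range(grid$centers)
    if (any(planted_bands$center < rng[1] | planted_bands$center > rng[2]))
      stopf("planted band centers must lie within the wavelength grid")
    if (any(planted_bands$width <= 0)) stopf("planted band widths must be > 0")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (scatter_sd < 0) stopf("scatter_sd must be >= 0")
  if (length(response_range) != 2L || response_range[1] >= response_range[2])
    stopf("response_range must be (min, max) with min < max")
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 planted_bands = planted_bands,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 scatter_sd = scatter_sd, flat_baseline = isTRUE(flat_baseline),
                 response_range = response_range, analyte = analyte,
                 units = units, grid = grid),
            class = "simulation_config")
}

#' Sampling design of a multi-stage greenhouse trial
#'
#' @param treatments Character vector of treatment labels.
#' @param samples_per_treatment Integer vector (recycled) of samples
#'   collected per treatment within each stage.
#' @param stages Character vector of growth-stage labels.
#' @param leaves_per_sample Leaves pooled into one sample.
#' @return An object of class `sampling_design`.
#' @details The default reproduces a tomato nitrogen-gradient trial: nine
#'   treatments at 25 samples plus one at 20 per stage (245/stage), three
#'   stages (735 samples), six leaves per sample (4410 leaves).
#' @export
sampling_design <- function(treatments = c(paste0("N", seq(20, 180, by = 20)), "N200"),
                            samples_per_treatment = c(rep(25L, 9), 20L),
                            stages = c("seedling", "flowering", "fruiting"),
                            leaves_per_sample = 6L) {
  if (length(treatments) == 0L) stopf("design must contain at least one treatment")
  if (length(stages) == 0L) stopf("design must contain at least one stage")
  counts <- rep_len(as.integer(samples_per_treatment), length(treatments))
  if (any(counts < 1L) || !is_count(leaves_per_sample))
    stopf("all design counts must be positive integers")
  structure(list(treatments = treatments, samples_per_treatment = counts,
                 stages = stages, leaves_per_sample = as.integer(leaves_per_sample)),
            class = "sampling_design")
}

#' Enumerate every sample of a sampling design
#'
#' @param design A [sampling_design()].
#' @return Data frame with one row per sample and columns `stage`,
#'   `treatment`, `sample_id`; `sum(samples_per_treatment) * length(stages)`
#'   rows in total.
#' @examples
#' nrow(enumerate_design(sampling_design()))  # 735
#' @export
enumerate_design <- function(design) {
  if (!inherits(design, "sampling_design")) stopf("`design` must be a sampling_design")
  per_stage <- data.frame(
    treatment = rep(design$treatments, design$samples_per_treatment),
    replicate = unlist(lapply(design$samples_per_treatment, seq_len)))
  out <- do.call(rbind, lapply(design$stages, function(s)
    cbind(stage = s, per_stage)))
  out$sample_id <- sprintf("%s_%s_%02d", out$stage, out$treatment, out$replicate)
  out$replicate <- NULL
  rownames(out) <- NULL
  out
}

# Leaf-like baseline reflectance shape: dark visible region, green bump at
# 550 nm, red edge near 715 nm rising to the NIR plateau at `level`.
baseline_spectrum <- function(cfg) {
  lam <- cfg$grid$centers
  if (cfg$flat_baseline) return(rep(cfg$baseline_level, length(lam)))
  cfg$baseline_level * (0.18 + 0.10 * exp(-(lam - 550)^2 / (2 * 30^2)) +
                          0.82 * stats::plogis((lam - 715) / 18))
}

# Total planted absorption profile per unit analyte at each grid center.
planted_profile <- function(cfg) {
  lam <- cfg$grid$centers
  prof <- numeric(length(lam))
  if (nrow(cfg$planted_bands) > 0)
    for (b in seq_len(nrow(cfg$planted_bands))) {
      bb <- cfg$planted_bands[b, ]
      prof <- prof + bb$effect * exp(-(lam - bb$center)^2 / (2 * bb$width^2))
    }
  prof
}

#' Channels carrying a planted signal
#'
#' Channels whose per-unit absorption amplitude is at least half the maximum
#' planted amplitude; the ground truth for selector recovery tests.
#'
#' @param cfg A [simulation_config()].
#' @param indices Optional channel subset (e.g. a cropped window) in which to
#'   express the result; defaults to the full grid.
#' @return Integer channel indices.
#' @export
planted_channels <- function(cfg, indices = seq_along(cfg$grid$centers)) {
  prof <- planted_profile(cfg)[indices]
  if (max(prof) <= 0) return(integer(0))
  which(prof >= max(prof) / 2)
}

#' Simulate a table of leaf spectra with analyte-driven absorption
#'
#' @param cfg A [simulation_config()].
#' @param design Optional [sampling_design()] supplying sample metadata; used
#'   when its total sample count equals `cfg$n_samples`.
#' @return List with elements `spectra` (a [spectra_table()]) and `response`
#'   (a [response_vector()]). Deterministic given `cfg$seed`.
#' @export
simulate_spectra <- function(cfg, design = NULL) {
  if (!inherits(cfg, "simulation_config")) stopf("`cfg` must be a simulation_config")
  n <- cfg$n_samples
  p <- length(cfg$grid$centers)
  prof <- planted_profile(cfg)
  base <- baseline_spectrum(cfg)
  out <- with_seed(cfg$seed, {
    y <- runif(n, cfg$response_range[1], cfg$response_range[2])
    gain <- if (cfg$scatter_sd > 0) 1 + rnorm(n, 0, cfg$scatter_sd) else rep(1, n)
    noise <- if (cfg$noise_sd > 0)
      matrix(rnorm(n * p, 0, cfg$noise_sd), n, p) else 0
    clean <- matrix(base, n, p, byrow = TRUE) - outer(y, prof)
    refl <- clean * gain + noise
    list(y = y, refl = refl)
  })
  refl <- pmin(pmax(out$refl, 0), 1)
  meta <- NULL
  if (!is.null(design)) {
    rows <- enumerate_design(design)
    if (nrow(rows) == n) meta <- rows
  }
  list(spectra = spectra_table(refl, cfg$grid, meta),
       response = response_vector(out$y, cfg$analyte, cfg$units))
}

#' Simulate a hyperspectral cube of a single leaf
#'
#' Builds an H x W x B reflectance cube containing one elliptical leaf over a
#' flat dark background (reflectance 0.02 at every band). Inside the leaf,
#' each pixel's spectrum follows the same absorption model as
#' [simulate_spectra()], driven by a smooth spatial concentration field with
#' optional vein and leaf-base depressions (veins and the leaf base carry
#' lower analyte contents than the lamina).
#'
#' @param cfg A [simulation_config()]; `n_samples` is ignored.
#' @param shape Length-2 integer `(H, W)`, both >= 8.
#' @param leaf List with `center` (row, col) and `radii` (row, col semi-axes
#'   in pixels) of the leaf ellipse. Radii of 0 give an all-background cube.
#' @param veins List controlling depressions, or `NULL` for none:
#'   `main_width` (px), `depth` (fractional concentration drop on the main
#'   vein), `n_secondary`, `secondary_depth`, `base_depth`, `base_fraction`
#'   (fraction of the major axis treated as leaf base).
#' @param field `"gradient"` (default, smooth base-to-tip ramp over the
#'   analyte range) or `"constant"` (the range midpoint everywhere).
#' @return List with `cube` (a [hypercube()], calibrated) and `truth` (a
#'   [concentration_map()] holding the generating field, background `NA`).
#' @export
simulate_cube <- function(cfg, shape = c(48L, 48L),
                          leaf = list(center = NULL, radii = NULL),
                          veins = list(main_width = 1, depth = 0.3,
                                       n_secondary = 3, secondary_depth = 0.2,
                                       base_depth = 0.25, base_fraction = 0.15),
                          field = c("gradient", "constant")) {
  field_kind <- match.arg(field)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 8L || W < 8L) stopf("cube shape must be at least 8 x 8")
  ctr <- leaf$center %||% c((H + 1) / 2, (W + 1) / 2)
  rad <- leaf$radii %||% c(floor(H / 2) - 2, floor(W / 2) - 2)
  if (any(rad < 0)) stopf("leaf radii must be >= 0")
  if (any(rad > 0) &&
      (ctr[1] - rad[1] < 1 || ctr[1] + rad[1] > H ||
       ctr[2] - rad[2] < 1 || ctr[2] + rad[2] > W))
    stopf("leaf ellipse exceeds the %d x %d frame", H, W)

  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- if (all(rad > 0)) {
    ((rows - ctr[1]) / rad[1])^2 + ((cols - ctr[2]) / rad[2])^2 <= 1
  } else matrix(FALSE, H, W)

  lo <- cfg$response_range[1]; hi <- cfg$response_range[2]
  # Smooth base-to-tip gradient along the major axis, scaled to the analyte
  # range; u in [-1, 1] from leaf base (low) to tip (high).
  major <- which.max(rad)
  u <- if (major == 1) (rows - ctr[1]) / max(rad[1], 1) else (cols - ctr[2]) / max(rad[2], 1)
  field <- if (field_kind == "constant") {
    matrix((lo + hi) / 2, H, W)
  } else {
    lo + (hi - lo) * (u + 1) / 2
  }
  if (field_kind == "gradient" && !is.null(veins) && any(mask)) {
    minor_d <- if (major == 1) abs(cols - ctr[2]) else abs(rows - ctr[1])
    on_main <- minor_d <= veins$main_width
    field[on_main] <- field[on_main] * (1 - veins$depth)
    if (veins$n_secondary > 0) {
      along <- if (major == 1) rows - ctr[1] else cols - ctr[2]
      for (k in seq_len(veins$n_secondary)) {
        offset <- (k - (veins$n_secondary + 1) / 2) * (2 * max(rad) / (veins$n_secondary + 1))
        on_sec <- abs(minor_d - abs(along - offset)) <= veins$main_width / 2
        field[on_sec] <- field[on_sec] * (1 - veins$secondary_depth)
      }
    }
    at_base <- u <= -1 + veins$base_fraction
    field[at_base] <- field[at_base] * (1 - veins$base_depth)
  }
  field <- pmin(pmax(field, lo), hi)
  field[!mask] <- NA_real_

  p <- length(cfg$grid$centers)
  prof <- planted_profile(cfg)
  vals <- array(0.02, dim = c(H, W, p))
  idx <- which(mask)
  if (length(idx) > 0) {
    base <- baseline_spectrum(cfg)
    spec <- with_seed(cfg$seed, {
      s <- matrix(base, length(idx), p, byrow = TRUE) - outer(field[idx], prof)
      if (cfg$scatter_sd > 0)
        s <- s * (1 + rnorm(length(idx), 0, cfg$scatter_sd))
      if (cfg$noise_sd > 0)
        s <- s + matrix(rnorm(length(idx) * p, 0, cfg$noise_sd), length(idx), p)
      s
    })
    spec <- pmin(pmax(spec, 0), 1)
    for (b in seq_len(p)) {
      plane <- vals[, , b]
      plane[idx] <- spec[, b]
      vals[, , b] <- plane
    }
  }
  cube <- hypercube(vals, cfg$grid, calibrated = TRUE)
  truth <- concentration_map(field, mask, range = c(0, hi),
                             units = cfg$units, analyte = cfg$analyte)
  list(cube = cube, truth = truth)
}
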