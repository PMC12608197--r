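---
title: "Coarse-fine-optimal wavelength selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-fine-optimal wavelength selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfoselect)
```

This vignette explains the science behind `cfoselect`: the models and
procedures, the parameters that matter, what the synthetic data generator
does and does not emulate, the numerical choices, and the package's known
limitations. All statements about behaviour are the ones the test suite
computes; nothing here is an empirical claim beyond what the tests assert.

## The measurement model

A VNIR push-broom imager records an H x W x B cube of sensor counts on a
uniform wavelength grid (the default grid, `vnir_grid()`, spans
380-1001.6 nm in 856 bands at 0.727 nm). Raw counts become reflectance by
the white/dark reference ratio

$$R = \frac{R_0 - R_b}{R_w - R_b},$$

applied element-wise (`radiometric_correct()`); the identities `R = 1` when
the target equals the white reference and `R = 0` at the dark floor are the
correctness anchors, and the operation is invariant to any common gain on
the three inputs. Channels near the detector edges are unstable, so
modelling is restricted to the 430-900 nm window.

**Window channel-count convention.** On the default grid an inclusive
`430 <= lambda <= 900` rule retains 647 centers, but the topmost one
(899.805 nm) lies within half a sampling interval of the cut.
`crop_window()` treats such a channel as straddling the boundary and drops
it, giving the 646-channel window (430.163-899.078 nm) that all percentage
bookkeeping uses. The drop is conditional: a window spanning the whole grid
is the identity, and a sliver window keeps its single channel rather than
erroring out. This convention favours the definitional channel count over
the printed endpoints because every downstream "share of the window"
statistic divides by it.

## Preprocessing

Three per-spectrum steps compose in the order Savitzky-Golay, SNV,
detrending (`default_preprocess()`):

* **Savitzky-Golay** (`step_sg(order = 1, window = 5)`): local
  least-squares polynomial refit removing high-frequency sensor noise.
  A window of 5 with order 1 is the smallest setting that actually smooths;
  instrument software sometimes reports an additional "frame length"
  parameter of its FIR implementation, which does not change the
  least-squares definition and is not a parameter here.
* **SNV** (`step_snv()`): per-spectrum standardization `(x - mean)/sd`,
  removing multiplicative scatter from leaf glossiness and geometry. It is
  exactly affine-invariant and idempotent.
* **Detrending** (`step_detrend(order = 2)`): subtraction of a global
  least-squares polynomial over the wavelength axis, removing baseline
  drift from diffuse reflection. We implement detrending as a pure global
  baseline subtraction -- no derivative is taken. Derivative language in
  instrument-software descriptions of "DT" is a tooling artefact; a
  derivative would change the units and the channel count, while
  baseline-drift removal is the stated purpose. A `window` argument is
  accepted for configuration parity and ignored, since the fit is global.

All steps are strictly per-spectrum, so preprocessing commutes with row
permutation and cannot leak information across samples or between the
calibration and prediction sets.

## SPXY partitioning

`spxy_split()` partitions samples by Kennard-Stone farthest-point selection
on the joint distance `d = dx/max(dx) + dy/max(dy)` (Euclidean in the
spectra, absolute difference in the response). The calibration set gets
`floor(n * ratio/(ratio + 1))` samples -- 551 of 735 at 3:1, with 184 left
for prediction. The procedure contains no randomness; ties in the
farthest-point step go to the lowest index for reproducibility. Because
selection is farthest-point, the response extremes land in the calibration
set, which is the behaviour one wants (the model never extrapolates on its
own prediction set). The split is computed per analyte by default: nitrogen
and chlorophyll have different y-spaces, so their joint distances differ
even on identical spectra.

## PLSR and the metric suite

The regression core is SIMPLS on mean-centered data (no unit-variance
scaling: preprocessing already sets the scale; centering-only is the
chemometrics default). The compiled kernel returns the whole coefficient
path, so cross-validation over component counts costs one pass per fold.
The latent-variable count is chosen by 10-fold cross-validation
(`cv_select_components()`), with folds formed as contiguous blocks of a
seeded shuffle; the cap is 10 components everywhere, applied globally for
comparability across selection stages. Metrics are
`R = cor(y_hat, y)`, `RMSE = sqrt(mean((y_hat - y)^2))` in analyte units,
and `RPD = sd(y)/RMSE` with the sample (n-1) SD of the same evaluation set;
RPD > 2 is the conventional usability bar. A zero RMSE reports `RPD = Inf`;
a constant prediction reports `R = NA` with a warning rather than a silent
zero.

Every selector scores a candidate channel subset by `RMSE_CV`: the minimum
over component counts of the 10-fold CV error of a PLSR restricted to that
subset. One fold assignment per selector call keeps subset scores
comparable within a run; iVISSA is the exception (below).

## The three selection stages

**Stage 1 -- coarse (intervals).** `irf_select()` searches sets of
contiguous windows (width 10 by default, starting from 20 equidistant
intervals) by a reversible-jump walk: add, remove, or shift one interval
per iteration. Additions must strictly lower `RMSE_CV`; removals may trade
a small error increase that anneals from 5% to 0 over the run, and the
proposal mix leans toward removal (0.2/0.45/0.35 add/remove/shift). Both
asymmetries exist because cross-validated error is nearly flat in
uninformative channels: a symmetric rule lets null intervals drift in and
out and inflates the selection frequencies. Frequencies are tallied over
the second half of the iterations (burn-in) and channels above the 0.5
frequency threshold are returned; threshold 0 returns the full window, and
a zero-iteration run returns the initial equidistant intervals.

`ivissa_select()` performs weighted bootstrap Monte Carlo sampling: every
channel starts at weight 0.5, sub-models include each channel with
probability equal to its weight, and weights move to each channel's
frequency among the best 10% of sub-models. Folds are re-randomized every
round so a channel that happens to fit one fold split cannot stay lucky.
Rounds stop at `max |dw| < 0.01` (a convergence tolerance taken from the
originating space-shrinkage literature) or a round cap. The final space
selection evaluates nested top-weight subsets by `RMSE_CV`, grows
contiguous intervals outward and backward-prunes, both with bounded passes.

A property of the frequency update worth knowing: a channel whose inclusion
does not change sub-model error has elite frequency equal to its current
weight -- the update is a martingale there, so weights of harmless-but-null
channels polarize only slowly (they matter only when channels genuinely
degrade the model, i.e. in the p >> n regime). The package therefore treats
the weights as a ranking signal and lets the final `RMSE_CV`-driven
selection, not a weight threshold alone, decide membership. Exactly
duplicated channels compete in the feedback and one copy survives -- the
desired redundancy-elimination behaviour.

**Stage 2 -- fine (model population analysis).** `cars_select()` runs 100
Monte Carlo iterations; each fits a PLSR on a random 80% of the calibration
rows (a conventional fraction), ranks survivors by absolute coefficient,
enforces the exponentially decreasing retention schedule (`cars_edf()`,
calibrated so run 1 keeps everything and the last run keeps 2), then
resamples among the kept channels proportionally to coefficient magnitude.
The run with minimal `RMSE_CV` wins. Its error trace falls while redundant
channels are shed and rises once informative ones start being forced out --
the classic interior minimum.

`boss_select()` bootstraps channels with probability proportional to
weights that are replaced each round by the accumulated normalized absolute
coefficient mass of the best 10% of sub-models (soft shrinkage: weights
shrink smoothly and sum to 1; a channel is only lost when its weight
underflows). `vcpa_select()` samples random binary channel combinations at
a fixed 10% inclusion ratio, shrinks the candidate pool geometrically to
100 channels over 50 iterations using elite inclusion frequencies, and
finishes with a direct search (nested top-frequency subsets; exhaustive
pairs and triples when the pool is small). Sub-model counts, elite
fractions, the BMS inclusion ratio and the final pool size are exposed as
configuration because the methods' sources state them only partially.

**Stage 3 -- optimal.** `iriv_select()` draws a random binary inclusion
matrix (500 rows at probability 0.5 by default), scores every row-subset,
and computes for each channel `DM = mean(RMSE_CV | in) - mean(RMSE_CV | out)`
with a Mann-Whitney U test between the two populations. `DM < 0` marks
informative channels (strong if p < 0.05, weak otherwise); `DM >= 0` marks
uninformative (p >= 0.05) or interfering (p < 0.05) ones, which are dropped
until none remain; a final backward elimination removes weak channels
one-by-one when removal lowers `RMSE_CV`. The sign convention is fixed so
that "negative DM means informative" holds literally. `ga_select()` is a
plain elitist GA over channel bitmasks capped at 30 set bits (repair by
random clearing), tournament selection, single-point crossover at 0.5,
bit-flip mutation at 0.01, stopping after 200 distinct subset evaluations
-- read as an evaluation budget, not a generation count. Elitism makes the
best-so-far fitness non-decreasing; a stagnation guard stops the loop when
the cached subset space is exhausted (as on tiny problems, where the GA
provably reaches the exhaustive optimum).

**Chained containment** is structural: each stage receives only its
parent's channels and `selection_result()` refuses a child that escapes its
parent, so `optimal` is always a subset of `fine` is a subset of `coarse`
is a subset of the window.

## The synthetic data generator

`simulate_spectra()` draws analyte values uniformly over an observed
response range (nitrogen 0.7374-7.6357 %, chlorophyll 0.2614-3.7026 mg/g
are the ranges used for defaults -- uniform because only the range
summaries are known, not the distribution) and builds reflectance as

> gain x (baseline(lambda) - sum_b effect_b x response x
> Gauss(lambda; center_b, width_b)) + noise,

clipped to [0, 1]. Defaults: 735 samples (245 per growth stage across
seedling/flowering/fruiting, the nine-plus-one treatment design of
`sampling_design()`), Gaussian absorption at the shared diagnostic bands
479 and 689 nm with 15 nm width (Gaussian, not Lorentzian -- the simplest
shape for broad pigment features), effect 0.01 reflectance per analyte
unit (chosen so the darkest visible-region dip never clips at the top of
the response range), sensor noise SD 0.005, and multiplicative scatter
gain SD 0.03.

Two deliberate realism features deserve explanation. The baseline is not
flat but leaf-shaped (dark visible region, green bump at 550 nm, red edge
near 715 nm, NIR plateau at `baseline_level`), and each sample carries a
multiplicative scatter gain. Without them, the analyte-scaled dip is the
*only* source of per-spectrum variance, and SNV -- which divides by exactly
that variance -- cancels the signal identically, leaving nothing for any
selector to find. Real leaf spectra never have that degeneracy; the shaped
baseline and scatter reproduce the variance structure SNV exists to
normalize. `flat_baseline = TRUE` with `scatter_sd = 0` recovers the bare
dip-plus-noise model, which the unit tests use where analytic statements
(perfect correlation, strict monotonicity, truly-null channels) are
asserted.

What the generator does **not** emulate: radiative-transfer leaf optics
(no PROSPECT-style scattering physics), wavelength-correlated noise,
instrument stray light, multiple overlapping analytes, or multi-leaf
scenes. Passing tests therefore demonstrate the machinery -- recovery of
planted structure under the stated noise -- not field performance on real
leaves.

`simulate_cube()` paints one elliptical leaf over a flat 0.02-reflectance
background (flat so mask segmentation is exactly testable), drives pixel
spectra with a smooth base-to-tip concentration gradient, and depresses
the field along a main vein, secondary veins and the leaf base, emulating
the lower analyte content of vascular tissue. It returns the true field so
inversion tests can measure recovery (rank correlation > 0.9 at default
noise).

## Pixel-wise inversion and mapping

`predict_pixelwise()` applies the tabular preprocessing pipeline to each
masked pixel's full-window spectrum and only then extracts the model's
channels, so a pixel whose spectrum equals a calibration sample's mean
spectrum reproduces the tabular prediction to 1e-10 -- the equivalence the
tests pin. Background pixels carry an `NA` sentinel and are excluded from
every later computation. Negative predictions are kept in the stored map
and only clipped at rendering.

The enhanced Lee filter (`lee_enhanced()`, 3x3 window, damping 1,
homogeneity 0.52, heterogeneity 1.73) classifies each masked neighbourhood
by its coefficient of variation `C = sd/|mean|`: homogeneous windows take
the local mean, heterogeneous ones are preserved, and the transition zone
blends `w x mean + (1 - w) x pixel` with
`w = exp(-damping (C - homog)/(heterog - C))`, which is continuous at the
homogeneous boundary and convex, so output never leaves the window's
min-max range. The filter runs on the floating-point concentration map,
not an 8-bit quantization -- the lossless choice. Rendering maps the
display range (nitrogen 0-7.64 %, chlorophyll 0-3.70 mg/g by convention,
overridable) onto a monotone blue - light blue - green - yellow - orange -
red ramp with background in neutral grey and an optional colorbar strip.

## Numerical choices and degenerate inputs

* SIMPLS deflation stops when the residual covariance norm underflows
  (1e-12 relative); requested components beyond the effective rank repeat
  the last valid solution instead of producing noise.
* Constant responses are errors everywhere (PLSR, SPXY, selectors) -- they
  make covariance, joint distance and CV error meaningless.
* `RMSE_CV` ties between subsets break toward the smaller subset, then
  lowest channel indices; farthest-point and argmin ties take the first
  (lowest) index. All stochastic routines take an explicit seed, preserve
  the caller's RNG state, and reproduce bit-identical results under the
  same seed.
* The test suite and the examples run the cascade at reduced iteration
  budgets (roughly 100-150 sub-models or iterations per selector, problem
  sizes of 60-150 samples by 40-150 channels for unit tests, and one
  735 x 646 full-design run for the twelve-strategy comparison); budgets
  are configuration, not algorithm, and the defaults remain the full-scale
  settings.

## Known limitations

* PLSR only: no nonlinear learners, no uncertainty intervals on
  predictions or on selection stability.
* The selectors optimize cross-validated error on the calibration set;
  with very few samples the selected subsets inherit CV noise (mitigated,
  not removed, by iVISSA's per-round fold refresh).
* Weight saturation in iVISSA requires channels whose inclusion measurably
  degrades sub-models; in well-conditioned n > p settings its weights
  separate directionally but do not reach 0/1, and the RMSE_CV-driven
  final selection does the deciding.
* ENVI I/O covers the BIL float32 dialect the package writes; other
  interleaves or integer types are out of scope, as are geometric
  calibration and multi-leaf instance separation.
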