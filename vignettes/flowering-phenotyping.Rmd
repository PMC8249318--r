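---
title: "Flowering phenotyping from UAV multispectral imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowering phenotyping from UAV multispectral imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowerpheno)
```

## The measurement model

The package treats flowering quantification as a four-stage measurement:

1. **Index maps.** Each acquisition is a co-registered five-band reflectance
   grid (blue, green, red, red-edge, NIR; unitless, nominally in [0, 1]).
   Flowering signal is carried by the normalized difference yellowness index
   NDYI = (green − blue)/(green + blue): carotenoids in yellow petals absorb
   blue and reflect green, while green canopy keeps the two bands closer
   together and scores low. NDVI, GNDVI and NDRE are computed with the same
   machinery; they are screening covariates rather than flowering detectors
   (red contamination from yellow petals actually *depresses* NDVI during
   bloom), but a complete screening layer needs them.

2. **Thresholding.** One NDYI threshold per campaign (site-year) separates
   flowering from non-flowering pixels, with strict `>` so a pixel exactly
   at the threshold is not flowering. This mirrors the field workflow, where
   the cutoff is chosen once per year against RGB composites; thresholds of
   0.45–0.59 are typical for canola. `suggest_threshold()` (256-bin Otsu, or
   a type-1 quantile) provides a reproducible starting point but is advisory
   only — it is never applied implicitly, because an automatic threshold
   silently shifting between years would change the meaning of every count.

3. **Zonal counting.** A plot's count is the number of threshold-exceeding
   pixels whose *centers* fall inside the plot polygon (0-based (row, col)
   coordinates, centers at integers). Counts are raw pixel numbers, not
   areas: that is what the downstream regressions are calibrated on, and
   pixel size is carried in metadata for users who need to normalize across
   flights at different altitudes.

4. **Temporal integration.** Each plot's series is summarized by the area
   under the flowering progress curve with a first-observation baseline,
   AUFPC = Σ ((F_i + F_{i+1})/2 − F_1)(t_{i+1} − t_i), in pixel-days. The
   baseline term removes each line's starting level, so genotypes that were
   already flowering at the first flight are not credited for it. Two
   consequences are accepted deliberately: a constant series integrates to
   exactly zero, and a series that dips below its first observation can go
   *negative*. Negative AUFPC is reported, not clamped — it is information
   (flowering declined from the start), and clamping would bias the yield
   regression. Integration runs on the observed irregular flight grid
   (gaps of 4–7 days are typical); no curve is fitted and no dates are
   imputed, so a plot's AUFPC is defined from its first *available*
   observation, with short series reported per plot rather than failing the
   batch.

## The two regression layers

**Counts vs manual counts (per date).** Manual flower counts are regressed
on pixel counts with a *zero-intercept* model: before flowering commences
there are no flowering pixels, so the origin is a physical constraint. The
reported R² uses the uncorrected total sum of squares (1 − SSE/Σy²), the
standard through-origin convention. This is documented loudly: it is not
comparable to the centered R² of intercept models and is typically higher;
on degenerate data it can leave [0, 1], in which case the value is reported
as-is with a `defined = FALSE` flag rather than clipped, so downstream code
can decide. Imagery and count dates rarely coincide, so plots are matched by
nearest reference date within a tolerance (default 4 days — half the longest
typical flight interval, so a count is never matched across two flights);
unmatched plots are dropped with a log line rather than silently.

**Yield vs AUFPC (per campaign).** Seed yield has a large base level
independent of flowering signal, so this layer uses ordinary least squares
*with* intercept and centered R². A per-date screening table (yield against
single-date counts, with F-test significance classes at 0.05/0.01/0.001)
reproduces the motivating comparison: single-date fits are erratic because
lines peak at different times, while the integrated statistic uses the whole
season.

## The synthetic campaign generator

Field imagery of this kind is rarely shareable at repository scale, so the
generator is a first-class module: every pipeline stage is tested against
campaigns with exact ground truth.

What it emulates: plots as per-pixel mixtures of flower, leaf and soil
(optionally pod); per-genotype unimodal flowering curves over Julian dates;
flower pixels spectrally separated by high green / low blue; additive
Gaussian band noise truncated at zero; manual counts proportional to true
flower pixels with multiplicative noise; and yield linear in true AUFPC with
additive noise.

Key defaults, chosen once as realistic study conditions:

* **50 plots × 7 weekly dates (days 178–220), 20×20 px plots.** A typical
  single-location trial block and flight cadence through the flowering
  window; small enough that a full campaign renders in about a second.
* **Phenology** per plot: amplitude (peak flower fraction) uniform in
  [0.3, 0.8], peak day in [190, 205], Gaussian-bell width in [6, 12] days —
  a 2–6 week flowering window across a diverse panel. The bell is pluggable;
  nothing downstream assumes its shape.
* **Signatures**: flower NDYI 0.75, leaf 0.25, soil 0.11, pod 0.50, so any
  threshold in the field's 0.45–0.59 range separates flower from canopy on
  noise-free data. The leaf green/blue levels (0.15/0.09) were set by noise
  propagation: with band noise sd 0.02 the leaf-NDYI standard deviation is
  ≈ 0.12, keeping leaf pixels ~2σ below a 0.5 threshold so misclassification
  stays at the few-percent level rather than dominating the calibration.
* **Noise**: band sd 0.02, manual-count CV 10%, yield noise 5% of the
  yield-signal range — enough to make recovery non-trivial without drowning
  the structure.
* **Calibration truth**: 1.6 flowers per flowering pixel; yield =
  1384.7 + 0.0026 × AUFPC + ε. These magnitudes match published field-scale
  fits, so recovered slopes are on a familiar scale.
* **Pods (off by default)**: after a plot's peak, the canopy share of pods
  ramps linearly to `pod_max` at the last flight. Pod NDYI sits *at* the
  example threshold, so with noise roughly half of pod pixels cross it —
  inflating late-date counts with signal unrelated to manual flower counts.
  This reproduces, qualitatively, the early/peak-strong late-weak R²
  pattern seen in the field, and is asserted only as a monotone comparison.

Class assignment is per-pixel independent (no spatial clumping). Counting is
clump-invariant, so this costs no generality for the quantities tested; it
does mean the images are not visually realistic textures. Other features of
real data the generator does not emulate: georeferencing error and plot
misalignment, illumination/BRDF drift within and between flights, mixed
boundary pixels, and spatially correlated field trends in yield. Passing
tests therefore demonstrate that the *pipeline arithmetic and statistics*
are correct under the stated noise model — not that any particular field
threshold or calibration transfers to new imagery.

Determinism: all draws derive from the master seed through per-plot and
per-plot-per-date substreams, so output is reproducible byte-for-byte, a
plot's truth does not depend on how many plots follow it in the config, and
the caller's RNG state is untouched.

## Numerical and interface choices

* **Pixel-in-polygon rule.** Even-odd ray crossing with the standard
  half-open convention (edges with `(y_i > p) != (y_j > p)`, strict
  `x < x_intersect`). Every pixel center is assigned to exactly one polygon
  of a partition that shares edges, which makes count additivity over plot
  subdivisions exact — the property the tests assert — with no epsilon
  tuning.
* **Raster storage.** Float-sample TIFFs from photogrammetry tools are read
  as-is. Files written by the package store 32-bit integer samples under a
  linear map v = 4s − 1 (resolution ~1e-9 reflectance), with stored 0 — i.e.
  v = −1, outside any physical range — as the nodata sentinel; the reader
  auto-detects which convention applies from the TIFF sample-format tag.
  Decoded magnitudes below 2e-9 are snapped to exact zero so that a
  truncated-at-zero band value cannot come back as −1e-9 and flip index
  validity at the ±1 bounds.
* **Out-of-range reflectance** (calibration artifacts slightly outside
  [0, 1]) is retained, not clipped, and reported; indices invalidate any
  pixel whose denominator is ≤ 0 or whose value leaves [−1, 1]. Invalid
  pixels are masked out of both flowering and non-flowering tallies — a
  shadowed pixel must not count as "not flowering".
* **Degenerate regressions.** All-zero predictors (pre-flowering dates)
  raise an informative error in a single fit and become a logged skip in the
  pipeline; all-zero responses return slope 0 with an undefined-R² flag.
* **Otsu tie-break.** The 256-bin histogram spans the observed range; the
  lowest bin edge maximizing between-class variance is returned. Between
  well-separated modes the objective is nearly flat, so tests compare
  achieved objective values, not argmin locations.
* **Dates** are day-of-year numbers within one season; cross-year series
  are out of scope (each site-year is a separate campaign with its own
  threshold).

## Problem sizes

The shipped tests run campaigns of 2–50 plots and property checks of
1000 random series/images; the full suite completes in well under a minute,
and `scripts/acceptance.R` (three 50-plot campaigns plus the 1000-series
oracle check) in a few seconds. Scene size grows linearly in plot count and
date count; a 56-plot, 7-date season at field GSD is a few million pixels
per band and runs in seconds on one core.

## Known limitations

* No sub-pixel unmixing: a mixed flower/leaf boundary pixel is whatever the
  threshold says it is. The single-threshold method inherits this from the
  field workflow it reproduces.
* No radiometric or geometric pre-processing: inputs are assumed calibrated
  and co-registered (upstream photogrammetry), and no lattice/incomplete-
  block adjustment is applied to ground data.
* The yield layer is a single-predictor linear model by design; multivariate
  yield modelling (multiple indices, pod-stage reflectance) is out of scope.
* GeoJSON is the only polygon dialect read natively, and georeferencing is
  carried as an explicit affine geotransform rather than parsed from GeoTIFF
  tags.
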