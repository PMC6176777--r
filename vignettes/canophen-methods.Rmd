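---
title: "Methods: shadow-aware trait extraction and exponential biomass modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shadow-aware trait extraction and exponential biomass modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canophen)
```

## The measurement problem

A multirotor aircraft flying ~30 m above a nursery of small plots produces
two co-registered products: a five-band reflectance orthomosaic
(blue/green/red/red-edge/NIR, ~2 cm ground sampling distance, 16-bit
digital numbers with DN 32768 = 100% reflectance) and a digital surface
model (DSM, ~1.3 cm GSD) whose elevations include the canopy. From these,
each plot should yield a small set of traits — canopy height, canopy
cover, and mean vegetation indices — that stand in for destructive biomass
sampling and laboratory nitrogen/chlorophyll assays.

Two artifacts dominate if the extraction is done naively:

1. **Shadows invert the index contrast.** A cast shadow removes direct
   illumination but keeps diffuse sky light, which is relatively richer in
   the NIR. Normalized-difference indices such as NDVI therefore come out
   *higher* in shadow than over sunlit canopy, so plots bordered by taller
   neighbours would spuriously gain NDVI. The package's segmentation stage
   removes shaded and soil pixels with a single excess-green threshold
   (ExG = 2ρ_G − ρ_R − ρ_B; both soil and shadow sit low in ExG) before
   any spectral trait is averaged.
2. **No terrain model is delivered.** Plant height must come from
   DSM − DTM, but under a closed canopy the ground is invisible. The
   package reconstructs the terrain from the bare-soil strips that flank
   the field east and west: per raster row, the median DSM elevation in
   each strip, linearly interpolated between the two strip centres
   (constant beyond them). This assumes the field has only a gentle,
   approximately linear west–east trend — adequate for small flat fields,
   wrong for terraced or strongly sloped ones.

## Trait definitions

- Heights are (DSM − DTM) × 100 cm, clipped at 0 (terrain interpolation
  error can produce small negatives). Per plot, the 90th, 93rd, 95th and
  98th percentiles of *all* in-plot pixels (canopy and soil alike) are
  reported; `select_height_percentile()` picks the percentile that best
  correlates with manual measurements, breaking ties toward the lower
  percentile. Percentiles interpolate linearly between order statistics
  (`stats::quantile` type 7).
- Canopy cover is the sunlit-vegetation fraction of the plot's pixels —
  deliberately *after* shadow removal, so heavily shadowed plots read low.
- The eight vegetation indices follow their standard algebraic forms. RDVI
  is implemented with its defining square-root denominator,
  (ρ_NIR − ρ_R)/√(ρ_NIR + ρ_R); index tables occasionally misprint it as
  identical to NDVI, and that variant is available behind
  `rdvi_compat = TRUE`, but only the radical form behaves differently from
  NDVI and justifies treating the two as distinct predictors.
- A pixel belongs to a plot iff its centre lies inside the polygon, with a
  half-open boundary rule (left/bottom edges inclusive) so adjacent plots
  partition pixels with no sharing.
- Plot VI means use pixels that are in-plot *and* mask-true; a plot with
  zero sunlit pixels is flagged (`n_sunlit = 0`, VI means `NA`) rather
  than erroring, and downstream modeling drops it with a logged count.

## Statistical models

Biomass grows multiplicatively with canopy traits, so the package fits
exponential curves

Y = a · exp(Σⱼ bⱼ xⱼ),   a > 0,

by ordinary least squares on ln Y. This is the multiplicative-error model:
residuals act as a log-normal factor, which matches strictly positive
responses whose spread grows with the mean. It is closed-form and
reproducible; a nonlinear-least-squares refinement on the original scale
(additive error) is available via `method = "nls"` for sensitivity
analysis. Evaluation uses RMSE = √(Σ(Pᵢ−Mᵢ)²/n), the n−1 sample standard
deviation across fold RMSEs, and the Pearson correlation with its
two-sided t-transform p-value.

Model search follows the admissibility rule used in such trials: from the
candidate predictor correlation matrix, only pairs with |r| < 0.69 enter
multi-predictor models (strictly — a boundary pair at 0.68 is admitted,
one at 0.69 is not), plus caller-supplied larger sets whose internal pairs
all pass. Data are split 4:1 into train/test (seeded, uniform without
replacement; 363 samples split 290/73), models are validated by seeded
10-fold cross-validation (fold sizes differ by at most one; the reported
RMSE is the mean over folds), and treatment effects on CI_Green,
CI_RedEdge and NDRE are tested with the pooled-variance Student's t
(Welch optional). p-values are reported raw; a multiple-testing option is
deliberately not the default because the reference workflow reports raw
values. Whether the original split was stratified is unknowable, so
nothing downstream depends on split membership — only on its sizes and
seeding.

## What the scene generator emulates

`simulate_scene()` produces a field with *known* per-plot truth so that
every stage above can be validated end to end:

- **Design.** `n_reps` complete blocks stacked north–south; within each
  block the line × treatment combinations are randomized over a
  treatments-by-lines grid of 3 m × 3 m plots (defaults 24 × 2 × 8 = 384).
  Bare-soil margin strips (default 2 m) flank the field for terrain
  estimation.
- **Truth.** Per-line mean height (340–440 cm — the crop is 3.5–4.5 m
  tall late season), cover (0.55–0.90) and NDVI latent (0.70–0.88) are
  drawn once per line; plots add treatment shifts (+20 cm, +0.05) and
  plot-level noise. The NDRE latent carries the nitrogen signal: low-N
  mean 0.30, high-N +0.08, sd 0.04. Fresh and dry biomass come from the
  published three-predictor exponential models (PH, CC, NDRE) times
  log-normal noise (sd 0.05); leaf N (1.8 ± 0.4%) and chlorophyll
  (30 ± 8, relative units) are drawn with correlation 0.6 to the
  standardized NDRE latent. Dry biomass is capped below fresh.
- **Rendering.** Canopies are flat-topped strips along the four crop rows
  (0.76 m spacing), grown outward from the row centrelines until exactly
  `round(cover · n)` of the plot's pixels are canopy, with height jitter
  (sd 0.05 m). The canopy spectrum is inverted from each plot's latents:
  with NIR fixed at 0.50, red = NIR(1−NDVI)/(1+NDVI) and red-edge =
  NIR(1−NDRE)/(1+NDRE); blue 0.06 and green 0.13 are fixed. Soil is a
  dark reddish-brown spectrum (0.11, 0.09, 0.07, 0.18, 0.26): its high
  NIR/red ratio is what lets a simple multiplicative shadow model
  reproduce the field-observed index inversion. Additive reflectance
  noise (sd 0.005) precedes shadow casting.
- **Shadows.** A binary mask by ray casting on the DSM (block-averaged to
  the multispectral grid) at the configured sun position (default azimuth
  135°, elevation 70° — a near-noon summer sun at ~41° N). Shaded pixels
  have visible bands multiplied by 0.2 and red-edge/NIR by 0.7, which
  yields mean NDVI higher in shadow than over sunlit canopy while ExG
  drops well below the 0.046 threshold. An occluder must rise at least
  0.25 m above the sun ray to shade a pixel — a crude stand-in for
  penumbra and diffuse fill that also prevents centimetre-scale canopy
  roughness from self-shading entire plots; real inter-row and inter-plot
  shadows are tens of centimetres to metres of prominence and are
  unaffected. These optical constants were calibrated jointly, once,
  so that the generator exhibits the three properties the pipeline is
  tested against — shaded-NDVI inflation, shaded ExG below threshold, and
  canopy-cover recoverability within ±0.05 for ≥90% of plots — and then
  frozen.
- **Reproducibility.** All randomness flows from one root seed through
  named substreams (design, truths, render), so identical configuration
  and seed give bit-identical scenes and each stage can be regenerated
  independently.

What it does **not** emulate: radiative transfer, leaf-level 3-D
structure, panicles, mosaicking seams or nodata holes, multi-date growth
(one date per invocation), or within-field terrain roughness beyond the
linear trend. Passing tests on simulated scenes therefore demonstrate the
*algorithms* — segmentation, zonal statistics, terrain interpolation,
model fitting — not the field validity of any particular index-to-biomass
relationship.

## Numerical choices and degenerate inputs

- Reflectance encoding: DN = round(ρ · 32768) clamped to [0, 65535];
  decoding divides by 32768, so a DN round-trip is exact to 1/32768.
  Unbounded rasters (elevations) are stored as normalized float32 with
  offset/scale in a JSON sidecar; round-trip accuracy is float32 relative
  precision of the value range (~2⁻²⁴), not bit-exactness.
- Division by zero in ratio indices yields nodata at the pixel, never an
  exception; nodata propagates through plot means via removal.
- The DSM is block-averaged (mean of fine-pixel centres per coarse cell)
  onto the multispectral grid when a common grid is needed.
- Empty plot pixel sets are errors for height/cover primitives, but a
  polygon that simply misses the raster rasterizes to an empty set.
- Constant vectors make Pearson correlation undefined: `pearson_r()`
  raises an error, and `evaluate_on_test()` reports RMSE with `r = NA`
  plus a warning. A t-test between two zero-variance groups returns t = 0,
  p = 1 when the means agree (±Inf, p = 0 otherwise).

## Problem sizes

The test suite validates scenes at reduced size (typically 8–24 plots at
3–5 cm GSD, a few hundred thousand pixels), where a full simulate →
extract → model cycle takes a few seconds; the statistical checks use the
full 384-plot design for truth simulation (no rendering) and n = 2000
populations for coefficient recovery, averaged over 20 seeded replicates.
The default full-size scene (384 plots, 2 cm GSD, ~9 million multispectral
pixels) renders in minutes and is intended for interactive use rather than
routine testing.

## Known limitations

- The ExG threshold is global; scenes with unusually dark canopies or
  bright soils need re-tuning, and misclassified shaded vegetation lowers
  canopy cover exactly as it does in real imagery.
- Terrain interpolation is row-wise linear; fields with nonlinear
  north–south trends would need a denser soil-visibility model.
- The exponential fit assumes multiplicative noise; heavy additive sensor
  noise at low biomass would favour the `nls` variant.
- GeoTIFF georeferencing tags are not written; geometry travels in the
  world file / sidecar, which GIS tools that honour world files can read.
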