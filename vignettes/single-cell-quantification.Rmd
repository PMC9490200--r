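---
title: "Quantifying fluorescent cell populations with scfq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescent cell populations with scfq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfq)
```

## The problem

Many cell-biological readouts reduce to the fraction of cells in a monolayer
that carry a fluorescent marker: transfection efficiency (share of cells
expressing eGFP), virus infection rates with reporter viruses, and the
suppression of those rates by inhibitors. Counting cells by eye is slow and
ignores the intensity information; bulk (plate-reader style) intensity
measurements confound *how many* cells are positive with *how bright* they
are. `scfq` automates the per-cell route: find every cell, measure its
marker fluorescence, and split the single-cell intensity distribution into
negative and positive populations.

## The per-image model

An image is assumed to show a **monolayer** — a single layer of adherent
cells — with a nucleus stain in one channel and the marker in another.
Three observations carry the method:

* every cell has exactly one stained nucleus, so nuclei are reliable
  per-cell anchors;
* cell bodies have weak intrinsic **autofluorescence**, so cell-covered
  area can be told apart from empty substrate even for marker-negative
  cells;
* per-cell mean marker intensities of negative and positive cells differ
  by one or more orders of magnitude, so the **log10** intensity histogram
  shows two separable populations (or one population plus a tail).

The pipeline in `analyze_image()` implements this as: foreground mask →
nucleus seeds → seeded watershed → background correction → per-cell
measurement → log10 histogram → classification.

## Tunable parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `beta` | background threshold: smoothed composite intensity below which a pixel is cell-free | raw marker intensity | 15 |
| `omega` | seed sensitivity: minimum prominence of a nucleus-channel local maximum | raw nucleus intensity | 5 |
| `alpha` | classification offset above the non-fluorescent population peak | log10 decades | 0.4 |
| `n_bins` | log10 histogram bins | — | 64 |
| `min_area_px` | minimum region/speck/hole area | px | 30 |
| `smoothing_sigma` | Gaussian pre-filter | px | 2 |
| `exclude_border` | drop regions touching the image edge | — | `FALSE` |

`alpha = 0.4` corresponds to a ≈2.5-fold intensity gate above the
non-fluorescent mode. Border cells are kept (but flagged) by default
because the fluorescent fraction is a ratio: removing clipped cells biases
dense fields without improving the ratio. `auto_estimate_params()` offers
data-driven starting values (`beta` from the marker intensity mode plus
three robust spreads of the sub-mode pixels; `omega` as 5% of the nucleus
channel's dynamic range), intended for a first pass that is then refined by
inspecting the overlay and histogram.

## Design choices in the mask

The foreground mask thresholds a composite of both channels so that
marker-negative cells (autofluorescence only) and marker-bright cells are
both captured. Two numerical details matter:

* **Background anchoring.** Each channel enters as its excess over its own
  background level — estimated by the intensity mode, the most common
  pixel value in a sub-confluent image — normalized by its dynamic range
  (99.5th percentile minus mode), and the composite is mapped back to raw
  marker units so `beta` keeps intensity units. Normalizing by a raw
  percentile instead would scale the *background* of the dimmer channel up
  past `beta` whenever the two channels' dynamic ranges differ strongly
  (a bright GFP population easily spans 100× the nucleus stain's range).
* **Clipping before smoothing.** The composite excess is clipped at the
  equivalent of `2 * beta` before Gaussian smoothing. Without the clip,
  the smoothed skirt of a very bright cell crosses an absolute threshold
  several pixels outside the true cell edge, so the mask would grow with
  marker brightness; with it, the mask boundary is approximately the
  half-height contour of the (clipped) cell edge for any brightness.

Specks and holes smaller than `min_area_px` are removed/filled.

## Seeds and watershed

Nucleus seeds are local maxima of the smoothed nucleus channel inside the
mask with **prominence** at least `omega`, computed exactly via
0-dimensional persistence of the super-level sets (union-find over pixels
in decreasing intensity order). This matches the "noise tolerance" notion
of interactive maxima finders: a shoulder on a brighter nucleus only counts
as a separate cell if it rises at least `omega` above the saddle that
connects them. Plateaus contribute one seed at their centroid; seeds closer
than `2 * smoothing_sigma + 1` px are thinned (brightest kept).

Cells are then separated by a marker-controlled watershed flooded from the
seeds on the elevation surface `-(smoothed nucleus channel)`, restricted to
the mask. Elevation ties are broken by Euclidean distance to the claiming
seed, which makes the partition on flat elevation exactly the nearest-seed
(Voronoi) assignment — a property the test suite exploits as an independent
oracle (brute-force nearest-seed assignment must agree except within a
pixel of the bisectors). Both primitives are implemented in C++; all
tie-breaks are lexicographic in `(y, x)`, and the segmentation path is
fully deterministic (no randomness anywhere).

## Quantification and classification

Background is the median marker intensity outside the mask (robust to
bright debris); per-cell means are corrected by subtracting it, floored at
zero. Perimeters use a Crofton-style four-direction intercept estimate
(`P = π/8 (I_h + I_v + (I_d1 + I_d2)/√2)`), which is nearly unbiased on
rasterized discs; circularity `4πA/P²` is clamped to 1. Cells with
non-positive corrected intensity are kept in the tables (empty
`log10_intensity` field in the CSV) but excluded from the histogram and
always classified negative.

The classification cutoff is `alpha` decades above the **non-fluorescent
population peak** of the 3-bin moving-average smoothed histogram. The
reference peak is the highest-count smoothed local maximum among
*significant* peaks (at least 10% of the global maximum and at least 2
smoothed counts, i.e. a mode of roughly six cells or more) whose bin center
lies within one decade of `beta` — because the non-fluorescent population
sits just above the autofluorescence level that `beta` thresholds, while
fluorescent populations lie well above it. When no such peak exists (a
fully transfected or fully infected image has no visible negative
population), the cutoff falls back to `log10(10 * beta)` itself. Without
this anchor, a peak-relative rule applied to a single bright population
would measure the population against its own mode and report a near-zero
fraction for a 100% positive image. Consequences worth knowing:

* the `alpha` offset acts whenever a negative population is detectable; in
  the fallback branch the cutoff is `alpha`-independent, so "fraction → 0
  as `alpha` → ∞" holds only when a negative mode exists;
* the anchor assumes the non-fluorescent mode lies within one decade of
  `beta` and fluorescent cells above it — true whenever `beta` is set, as
  intended, just below the autofluorescence level.

## The synthetic data generator

`generate_monolayer()` emulates the statistical structure of a monolayer
mixing experiment: cell centers placed by rejection sampling with a minimum
spacing of 1.6× the mean cell radius, Gaussian nuclei (amplitude 500,
σ = nucleus radius/2), disc-shaped cell bodies carrying autofluorescence
(40) plus — for a chosen fraction of cells, exactly `round(n * f)` of them —
a lognormal marker signal (log10 mean 3.0, sd 0.25), and additive Gaussian
background (5 ± 2) on a 16-bit-like scale. Geometry defaults (cell radius
10 ± 1.5 px, nucleus radius 4 ± 0.5 px, 512×512 frames with 200 cells)
correspond to confluent HEK-like cells (~20 µm) at ~1 µm/px. Generation is
bit-exact under a fixed seed; mixing series derive per-image seeds from the
base seed.

What it does **not** emulate: optical point-spread functions, uneven
illumination, Poisson shot noise (the Gaussian background subsumes it at
this scale), non-circular morphologies, multilayer growth and debris.
Passing the synthetic validation therefore demonstrates the correctness of
the algorithmic chain under the model's assumptions — not robustness to
every artifact of real microscopy, which is why inspecting overlays and
histograms on real data remains part of the workflow.

## Dose–response fitting

The infected fraction under an inhibitor follows the one-parameter
Langmuir-type law `f(c) = 1/(1 + c/IC50)` (top fixed at 1, bottom at 0,
Hill slope 1). `fit_ic50()` minimizes the (optionally inverse-variance
weighted) sum of squares over `log10(IC50)` — concentrations typically span
five decades, so the log parameterization keeps the search well-scaled — by
a coarse grid refined with Brent's method (tolerance 1e-12; noiseless
curves are recovered to better than 1e-6 relative). Zero-concentration
controls enter as fixed `f = 1` anchors. The 95% confidence interval is a
case-resampling bootstrap (default 1000 replicates, mandatory seed,
order-statistic percentile convention); measured coverage in simulation at
σ = 0.05 noise is ≈0.91, the familiar mild under-coverage of percentile
intervals at modest n. The interval is widened to contain the point
estimate if a resampling quirk would place it outside.

## Problem sizes used in validation

The packaged validation runs a synthetic mixing series of 11 input
fractions (0–100% in 10% steps) × 3 replicates at ~200 cells per 512×512
image, at default and at low generator noise; density robustness is checked
at 50–1000 cells per 1024×1024 frame; IC50 recovery uses 100 simulation
repeats (σ = 0.05, 4 replicates per concentration) and CI coverage 150
repeats of 999 bootstrap replicates. These sizes give stable statistics
while keeping the whole suite fast on a laptop.

```{r example, eval = FALSE}
series <- generate_mixing_series(seq(0, 1, 0.1),
                                 synth_params(n_cells = 200, rng_seed = 1),
                                 n_replicates = 3)
analyze_mixing_series(series, analysis_params())$validation
```

## Known limitations

* Monolayers only: overlapping or multilayered cells violate the
  one-nucleus-one-region assumption and degrade the segmentation.
* The classification anchor ties the expected location of the negative
  population to `beta`; exotic settings (negative population more than a
  decade above `beta`) would require adjusting `beta` accordingly.
* Proprietary microscope formats (lif, czi) are out of scope; convert to
  multi-page TIFF first. OME metadata, z-stacks and time series are not
  handled.
* The perimeter estimator differs slightly from polygon-tracing
  implementations used by interactive tools; circularities agree to a few
  percent on convex shapes but are not bit-identical.
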