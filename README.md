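# scfq — single-cell fluorescence quantification for monolayer microscopy

`scfq` quantifies fluorescent cell populations in two-channel fluorescence
microscopy images of cell monolayers. It is aimed at experiments where the
readout is "what fraction of cells is fluorescent?": transfection
efficiency screens (e.g. the share of eGFP-expressing cells), virus
infection assays with GFP-reporter viruses, and inhibition experiments
where that fraction is tracked across inhibitor concentrations to estimate
an IC50.

## Method

Every image must contain a nucleus-stain channel (e.g. Hoechst 33342) and a
marker channel (e.g. GFP). Per image the pipeline runs:

1. **Foreground mask** — cell-covered area is separated from empty
   substrate by thresholding a smoothed, background-anchored composite of
   both channels at the background threshold **β** (raw marker intensity
   units). The weak intrinsic autofluorescence of cell bodies is what makes
   this possible; the nucleus channel keeps marker-negative cells in the
   mask.
2. **Seed detection** — cell centers are local maxima of the smoothed
   nucleus channel with peak prominence ≥ **ω** (the segmentation
   sensitivity).
3. **Watershed segmentation** — the foreground is partitioned into
   single-cell regions by a marker-controlled watershed flooded from the
   nucleus seeds on the inverted smoothed nucleus channel, so whole cell
   bodies (not just nuclei) are measured.
4. **Quantification** — background fluorescence (median marker intensity
   outside the mask) is subtracted from each cell's mean marker intensity;
   geometry (area, perimeter, circularity, centroid) is recorded per cell.
5. **Classification** — the histogram of log10 corrected intensities
   typically shows a non-fluorescent population near the autofluorescence
   level and a fluorescent population one or more decades higher. Cells at
   least **α** log10 decades above the non-fluorescent peak are classified
   fluorescent; the per-image fluorescent fraction is the primary readout.

Defaults `β = 15, ω = 5, α = 0.4` work for typical 16-bit-scale monolayer
images and can be auto-estimated per image (`auto_estimate_params()`).

Dose–response data (inhibitor concentration `c`, infected fraction `f`) are
fitted with the one-parameter Langmuir-type inhibition model

    f(c) = 1 / (1 + c / IC50)

by nonlinear least squares in log-concentration space, with a
case-resampling bootstrap percentile 95% confidence interval.

A ground-truthed synthetic image generator (`generate_monolayer()`,
`generate_mixing_series()`) emulates monolayer cultures — non-overlapping
Gaussian nuclei, autofluorescent disc-shaped cell bodies, a controllable
fluorescent fraction with lognormal brightness, Gaussian background — so
the whole pipeline is testable without microscope data.

## Worked example

```r
library(scfq)

# a synthetic monolayer: 200 cells, 40% fluorescent
g   <- generate_monolayer(synth_params(fluorescent_fraction = 0.4, rng_seed = 7))
res <- analyze_image(g$image, analysis_params(beta = 15, omega = 5, alpha = 0.4))
res$summary
#> <image_summary> 'synthetic': 200 cells, 83 fluorescent (41.5%), cutoff log10 = 2.001

head(res$cells[, c("cell_id", "x", "y", "area_px", "mean_corrected", "is_fluorescent")])

# dose-response: fit an IC50 with a bootstrap CI
d   <- inhibition_dataset(c(0.01, 0.1, 1, 10, 100, 1000),
                          c(1, 0.99, 0.92, 0.47, 0.09, 0.01))
fit_ic50(d, n_boot = 1000, rng_seed = 1)
#> <dose_response_fit> IC50 = 9.172 (95% CI 8.87 - 11.47), RSS = 0.0004443, n = 6
```

The summary line means: 200 cells were segmented, the log10 cutoff was
placed 0.4 decades above the non-fluorescent population peak (at 1.601),
and 83 cells (41.5%) lie above it — close to the generator's ground-truth
fraction of 0.40.

## Batch processing from the shell

```sh
Rscript inst/cli/scfq.R analyze --input images/ --output results/ \
    --ext tif --nucleus-channel 0 --marker-channel 1 \
    --beta 15 --omega 5 --alpha 0.4
```

All `.tif` files under `images/` (and subfolders) are analyzed; per image a
segmentation overlay PNG, a log10 histogram (CSV + PNG) and a per-cell CSV
are written, plus one `summary.csv` (image title, total cells, fluorescent
cells, fraction). Channel indices are 0-based. Subcommands `simulate`,
`validate-mixing` and `fit-ic50` generate synthetic series, regress
recovered against true fractions, and fit inhibition curves.

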