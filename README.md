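# ztrack3d

Label-free detection and tracking of single cells in time-lapse 3D
bright-field z-stacks.

Long-term imaging of cells inside fibrillar 3D matrices (collagen scaffolds
and similar biomimetic environments) is gentlest in plain bright-field mode:
no fluorescent labels, no phototoxic illumination. The cost is that cells
appear only as faint defocus patterns — bright above their focal plane, dark
below — buried in clutter from matrix fibrils. `ztrack3d` turns such stacks
into quantitative single-cell trajectories and morphology time series. It is
aimed at cell-migration labs running multi-day bright-field time-lapse
experiments on primary or otherwise label-resistant cells.

## Method

The core idea is to work with **1D z-intensity profiles** instead of 2D/3D
image templates. Let `I(x, y, ·)` be the intensity column at lateral pixel
`(x, y)`. From one manually chosen cell pixel and one background pixel, the
pipeline takes two reference profiles (`T_cell`, `T_bg`) and then, per frame:

1. **Detection** — pixel `(x, y)` is a cell pixel iff
   `corr(I(x, y, ·), T_cell) > corr(I(x, y, ·), T_bg)` (Pearson). An
   erosion-like **density filter** removes pixels with fewer than 20% cell
   neighbors in a 5×5 window; 8-connected components become cell candidates.
2. **Sub-voxel z** — for the central 50% of each candidate's pixels, the
   cell template is translated (0.25 µm grid) and linearly stretched
   (0.9–1.1), amplitude-matched, and compared to the measured profile by
   mean absolute difference; the median of the per-pixel optima is the cell's
   z, with an empirical 95% interval. Plane spacing is 5 µm; the estimator's
   median error on synthetic scenes is ≈ 0.1–0.2 µm.
3. **Shape** — region growing from the candidate seed, gated by Pearson
   correlation (≥ 0.8) between each frontier pixel's profile and the *seed's*
   profile, recovers the full footprint; image moments yield area,
   roundness (`4A/π·major²`), aspect ratio and orientation.
4. **Tracking** — greedy shortest-first nearest-neighbor linking in 3D
   (gate 30 µm per 10-min frame), with a replayable manual-edit layer
   (relink / split / merge) and per-track / per-population migration
   statistics.

A synthetic bright-field scene generator (`scene_spec()`, `render_stack()`,
`simulate_series()`) renders cells with an antisymmetric
derivative-of-Gaussian defocus signature, fibril clutter, axial illumination
structure and camera noise — with exact ground truth, so the whole pipeline
is verifiable without microscope data. See the methods vignette
(`vignettes/ztrack3d-methods.Rmd`) for the model, parameter meanings and
design rationale.

## Worked example

Simulate a 4-frame, 3-cell time-lapse, run the full pipeline, and compare
with ground truth:

```r
library(ztrack3d)

set.seed(7)
cells <- lapply(1:3, function(i) {
  start <- c(c(25, 75, 125)[i], c(30, 80, 45)[i], 62.5 + runif(1, -2.5, 2.5))
  steps <- matrix(runif(9, -3, 3), 3, 3); steps[, 3] <- steps[, 3] / 3
  cell_script(i, rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`)))
})
scene <- scene_spec(c(160, 120, 25), n_frames = 4, cells = cells, rng_seed = 11)
dir <- file.path(tempdir(), "demo")
simulate_series(scene, dir)            # frame_000*.tif + ground_truth.csv

gt <- ground_truth(scene)
g1 <- gt[gt$frame == 1 & gt$cell_id == 1, ]
cfg <- run_config(
  template_cell_xy       = round(c(g1$x_um, g1$y_um) / 0.87 + 0.5),
  template_background_xy = c(155, 115),
  template_ref_z_um      = g1$z_um)

tracks <- run_pipeline(dir, cfg, out_dir = file.path(dir, "out"))
tracks
#> <cell_tracks> 12 observation(s) in 3 track(s) over 4 frame(s), 0 edit(s)

migration_stats(tracks)
#>   track_id n_steps mean_speed_um_min path_length_um duration_min
#> 1        1       3         0.2555606       7.666819           30
#> 2        2       3         0.3252983       9.758950           30
#> 3        3       3         0.2583761       7.751284           30

subset(tracks$observations, frame == 1,
       c(track_id, x_um, y_um, z_um, area_um2, roundness, aspect_ratio))
#>  track_id   x_um  y_um z_um area_um2 roundness aspect_ratio
#>         1  25.04 30.02 65.0    201.3    0.9731        1.023
#>         2 125.07 45.10 63.5    199.1    0.9866        1.010
#>         3  75.01 80.02 61.0    200.6    0.9896        1.007
```

The scripted cells sat at (25, 30, 64.9), (75, 80, 60.9) and (125, 45, 63.2)
µm with radius 8 µm in frame 1: recovered centroids are within ~0.1 µm
laterally and ~0.3 µm axially (plane spacing 5 µm), and the areas match the
true disk (π·8² ≈ 201 µm²). `migration_stats()` reports per-step speeds in
µm/min (3D displacement over elapsed time); `population_stats()` adds
windowed population summaries with the standard slow (< 0.5 µm/min) and fast
(> 2 µm/min) fractions.

The pipeline writes `tracks.csv`, a resolved configuration copy and a run
log next to its outputs, and is byte-for-byte reproducible given the same
inputs and configuration. A thin command-line wrapper lives at
`inst/cli/ztrack.R` (`simulate` / `track` / `stats` subcommands).

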