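---
title: "Label-free 3D cell tracking from bright-field z-stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free 3D cell tracking from bright-field z-stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztrack3d)
```

## The problem

Long-term live imaging of cells embedded in fibrillar 3D matrices (such as
collagen I scaffolds) is best done in plain bright-field mode: fluorescent
labels and their illumination measurably reduce cell viability over multi-day
experiments, and several primary cell types resist labelling altogether. The
price is contrast. A cell in a bright-field z-stack is visible mainly through
its defocus signature — it appears bright on one side of its focal plane and
dark on the other — while collagen fibrils add faint, high-spatial-frequency
clutter throughout the volume.

`ztrack3d` detects and tracks such cells using **one-dimensional z-intensity
profiles** instead of 2D/3D image templates. The profile at a lateral pixel
$(x, y)$ is the vector of intensities along the depth axis. Because the
defocus signature travels with the cell along z and is largely independent of
the cell's lateral shape, a single pair of reference profiles — one taken on
a cell, one on empty background — suffices to classify every pixel of every
frame, regardless of cell size, shape or orientation.

## Pipeline

### 1. Detection by template correlation

The user selects (per experiment — the signature depends on the optics and
cell type) a *cell template* and a *background template*. A pixel is assigned
to a cell iff the Pearson correlation of its profile with the cell template
strictly exceeds its correlation with the background template; ties and
zero-variance (saturated/dead) columns fall to background. Pearson
correlation is invariant to gain and offset, so detection is insensitive to
illumination level and camera scaling.

The raw cell map contains isolated false positives from fibril diffraction.
A single-pass **density filter** removes a pixel when fewer than 20% of its
neighbors (Chebyshev radius 2, i.e. a 5×5 window minus the center; the
denominator shrinks at image borders) are themselves cell pixels. The 20%
threshold is the method's published rule; the neighborhood radius is a
configuration choice (radius 1 proved brittle against 2-pixel clutter).
Surviving pixels are grouped into 8-connected candidates; components below
`min_area_px` (default 9 px ≈ 7 µm² at 0.87 µm pixels) are dropped as
sub-cellular fragments.

Templates are extracted once (frame 1 by default) and reused for the whole
series. The profile is averaged over a 5×5 patch around the selected pixel:
a raw single column carries one camera-noise realization, and — because
linear resampling smooths that noise at non-integer shifts — leaving it in
the template creates spurious sub-voxel fit minima roughly half a
pixel-to-plane spacing away from the true position. Patch averaging
suppresses the artifact at no cost to the signature. Set
`template_patch_px = 0` to recover raw single-column extraction.

### 2. Sub-voxel axial localization

Axial sampling is coarse (5 µm planes versus 0.87 µm pixels, a ratio of
5.75), yet the cell's z-position is recoverable far below the plane spacing
because the whole signature shifts continuously with the cell. For each
candidate pixel, the cell template is

* translated along z on an exhaustive grid (step `dz/20` = 0.25 µm),
* linearly stretched about its reference z (factors 0.9–1.1 in steps of
  0.05) to absorb minor profile variations,
* resampled onto the measured grid by linear interpolation,
* amplitude-matched by least-squares gain and offset,

and compared to the measured profile by the **mean absolute difference** —
the area between the two curves. The translation minimizing this mismatch
gives the pixel's z. The exhaustive grid is deterministic and immune to
local minima; ties resolve to the smaller offset.

Two choices matter for accuracy:

* **Background detrending.** The static axial illumination structure of the
  stack does not translate with the cell, so leaving it in both curves
  rewards a zero offset and shrinks every estimate toward the template
  cell's own z. The pipeline therefore subtracts the background template
  from both the cell template and each measured profile before fitting.
* **Central voxels only.** Border pixels of a cell have weak, distorted
  z-signals (the cell boundary runs nearly parallel to z there), so only
  the 50% of candidate pixels nearest the lateral centroid enter the fit.
  Candidates below 4 pixels fall back to all pixels, with a log message.

The cell's z is the **median** of the per-pixel fitted values (robust to an
occasional bad column); the 95% confidence interval is the empirical
2.5–97.5 percentile range of those values. The percentile construction is
this package's choice — the underlying method promises *a* 95% interval
without fixing an estimator — so the test suite asserts a deliberately loose
coverage bound (≥ 80%) rather than nominal coverage. The absolute z scale is
anchored by `template_ref_z_um`, the z the template cell is taken to sit at;
when unknown, the template grid midpoint is used, which keeps all *relative*
z (and every tracking quantity) correct up to one constant.

On synthetic scenes with camera noise σ = 0.02 and clutter, the median
absolute z error of this estimator is well below the 0.5 µm target (the
acceptance script reports ≈ 0.1–0.2 µm over 50 cells with true z drawn
uniformly between two planes).

### 3. Shape by correlation-gated region growing

Detection deliberately misses cell borders. To recover the full footprint,
the region grows outward from the candidate's seed (the pixel nearest its
centroid) across 8-neighbors, admitting a pixel while the Pearson
correlation between its profile and the **seed pixel's own profile** stays
at or above `corr_threshold` (default 0.8; the method prescribes "high"
correlation without a number, so the value is exposed in the configuration
and recorded with every run). Using the seed profile rather than the global
template adapts the criterion to the individual cell. Growth is monotone in
the threshold, and 1-pixel-wide appendages with fibril-like profiles are not
captured — thin filopodia are a stated limit of the approach.

When two grown masks collide, each contested pixel goes to the cell whose
seed-profile correlation there is higher (ties to the earlier candidate) and
both cells are flagged `contact`. Cells closer than the axial interference
range (~50 µm) may already have merged into a single candidate upstream;
such regions are not split.

Morphology comes from the second central moments of the mask's pixel
centers, with the 1/12-pixel self-moment added so single-row masks behave
like solid bars: area $N \cdot dx \cdot dy$; equivalent-ellipse axes
$4\sqrt{\lambda_{1,2}}$; aspect ratio $\sqrt{\lambda_1/\lambda_2}$;
orientation = major-axis angle in $[-90°, 90°)$; roundness
$4A/(\pi \cdot \mathrm{major}^2)$. The roundness definition is ImageJ's,
chosen because the original validation compared automated morphology against
manual ImageJ measurements.

### 4. Trajectory reconstruction

Frame-to-frame linking is **greedy shortest-first nearest neighbor** on 3D
Euclidean distance: among all unmatched pairs, repeatedly link the closest
one within `max_disp_um` (default 30 µm per 10-min frame — a 3 µm/min gate,
several times typical macrophage speeds). This keeps the spirit of plain
nearest-neighbor linking while never assigning one detection twice, and it
recovers the true matching whenever each true pair is mutually nearest —
the classical validity condition that inter-frame displacement stays below
the inter-cell spacing. Under that condition (verified per frame in the test
suite) linking is exact; when it is violated, nearest-neighbor methods
cannot be trusted and errors appear, which is why the package also ships a
replayable manual-edit layer (`apply_edit`: relink / split / merge, each
validated against the trajectory invariants and appended to an edit log).
Gap closing is off by default (`max_gap = 0`); bridged gaps, when enabled,
use the true elapsed time in speed calculations. Cell division is not
modelled: a division appears as one ended plus two started tracks.

Migration statistics follow directly: step speed = 3D displacement / Δt,
per-track mean speed and path length, and per-window population summaries
(mean ± SD of per-cell mean speeds, fractions below 0.5 and above 2 µm/min —
the conventional slow/fast bins for macrophage populations).

## The synthetic scene generator

Every stage is tested against scenes with exact ground truth
(`scene_spec()`, `render_stack()`, `simulate_series()`). A scene renders as

* a uniform background level (default 0.5),
* a smooth axial illumination profile — an even quadratic (Legendre $P_2$)
  modulation with amplitude 0.08 at the stack ends — standing in for the
  depth-dependent illumination of real transmitted-light stacks. Being even
  around the stack midpoint it cannot imitate the odd defocus signature of
  a cell, but it gives cell-free columns the shared structure that makes a
  background template meaningful in the first place;
* per cell, a hard lateral disk (pixel-center inclusion, so ground-truth
  footprints are exact; a soft edge is available but off by default)
  carrying the canonical defocus signature
  $A \cdot (z/\sigma)\, e^{-z^2/(2\sigma^2)}$ — the simplest antisymmetric,
  parametric, bounded model of the bright-above/dark-below appearance.
  Defaults: radius 8 µm, amplitude 0.2, σ = 12 µm (a signature spanning a
  few tens of µm, consistent with axial interference between cells closer
  than ~50 µm);
* fibril clutter: thin line segments (10–30 px) confined to 1–2 z-planes,
  amplitude 0.05 (25% of the cell amplitude), 3 segments per 100×100 px
  tile, drawn once per scene because the matrix is static over a
  time-lapse;
* additive Gaussian camera noise (default σ = 0.02 on a [0, 1] scale),
  seeded per frame via substreams of the scene seed so any frame renders
  identically in isolation.

Default geometry mirrors the reference acquisition: 0.87 µm lateral and
5 µm axial voxels, 10-min frame interval, stacks of 25 planes in the test
scenes (the real instrument records 125).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: physically rigorous optics (no PSF convolution or
scattering model; real defocus signatures are asymmetric and
setup-dependent), intensity textures inside the cell footprint, cell
division, photobleaching and stage drift, and dense matrices whose fibril
contrast approaches the cell amplitude. Templates in the tests are selected
programmatically from a calibration scene with a known cell; on real data
template choice is a per-experiment manual step and the quality of that
choice directly bounds detection quality.

## Numerical choices and degenerate inputs

* Intensities are min-max normalized per stack before processing, so 8-, 12-
  and 16-bit inputs behave identically; Pearson correlation and the fit's
  affine gain matching make the pipeline indifferent to the absolute scale.
* Correlations are clamped to $[-1, 1]$ against floating-point overshoot.
* Classification ties go to background (conservative); zero-variance columns
  are logged and classified background.
* The fit requires the translated template to keep at least
  $\max(4, n_z/2)$ samples of overlap; offsets violating this are excluded,
  and a template with zero variance in the overlap is an error.
* Collinear masks are regularized by the pixel self-moment, so aspect ratio
  stays finite; masks below 4 pixels have no shape parameters.
* Link ties (equal distances) break deterministically by observation order;
  the whole pipeline is deterministic given inputs, configuration and seed,
  and reruns produce byte-identical track tables.
* TIFF output uses 32-bit samples; writing quantizes to ~2⁻³² — reruns of
  the pipeline from files are still exactly reproducible because every run
  reads the same quantized values.

## Problem sizes used in the tests

The shipped test and acceptance scenes use 48–256 px lateral extents, 25
z-planes and up to 10 cells over up to 8 frames: large enough that every
rule (density filtering, overlap handling, collision resolution, linking)
is exercised on realistic geometry, while the full suite runs in well under
five minutes. The axial-precision experiment uses 50 independent one-cell
stacks with true z drawn uniformly between two planes; the streaming
pipeline processes frames one stack at a time, so series length is bounded
by disk, not memory.

## Known limitations

* A single template pair detects cells within the axial capture range of the
  template's signature (roughly ±σ of correlation overlap); experiments
  whose cells spread over hundreds of µm in z need per-depth template
  selection, which the configuration supports but the package does not
  automate.
* Interfering cells closer than ~50 µm in z merge into one candidate and
  are only flagged, not separated.
* The nearest-neighbor linker has no motion model; fast cells or low frame
  rates require the manual edit layer (or an external linker).
* xy positions remain at pixel-centroid resolution; only z is refined
  sub-voxel.
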