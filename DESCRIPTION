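Package: ztrack3d
Title: Label-Free 3D Single-Cell Detection and Tracking in Bright-Field Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks non-labelled cells in time series of 3D
    bright-field image stacks acquired in fibrillar biomimetic matrices.
    Cells are found by Pearson correlation of per-pixel z-intensity profiles
    against manually selected 1D cell and background templates, cleaned with
    a density (erosion-like) filter, localized along z with sub-voxel
    precision by template fitting with translation and limited linear
    stretching, segmented by correlation-gated region growing, and linked
    into trajectories by greedy nearest-neighbor assignment. Includes a
    synthetic bright-field scene generator with exact ground truth, migration
    and morphology statistics, TIFF input/output, and a scriptable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
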