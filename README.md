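# macrovol

Volumetric macrophage segmentation and morphometry for cleared-tissue
light-sheet stacks.

## The scientific problem

Whole-mount clearing plus light-sheet microscopy yields 3D image stacks in
which immune cells must be quantified *around* specific anatomical
structures, not over the whole volume. Given a macrophage marker channel
and an integer label map of regions of interest (here two duct-like
structures, `ed` and `vva`), the pipeline answers:

- how many macrophages sit within a physical distance of each structure,
  and which structure does each cell belong to;
- how large is each cell (physical volume, equivalent-sphere radius), and
  is it compact (*ameboid*) or thin-branched (*ramified*) — distinguished
  by rasterized convex-hull **solidity** Vm/Vh;
- what fraction of each structure's volume is occupied by cells;
- how well do several human raters agree, voxel-wise (Fleiss kappa).

The processing chain follows the published recipe: per-ROI mask dilation
(exact anisotropic Euclidean distance transform), Otsu thresholding over
in-mask voxels, 26-connectivity 3D object labeling, strict removal of
objects under 100 voxels, and removal of volume outliers above
median + 3 × scaled MAD.

Because real stacks of this kind are not publicly deposited, the package
ships a synthetic **phantom generator** with exact ground truth (two
tubular ROIs wearing cuffs of ameboid and ramified cells), and the whole
chain is validated end-to-end against it: with the default noise-free
phantom, segmentation recovers every cell voxel-for-voxel.

## Worked example

```r
library(macrovol)

cfg <- default_config()
# dilation radius that provably covers the whole periductal cell cuff
cfg$masking$dilation_um <- phantom_cuff_dilation_um(cfg$phantom)
report <- run_pipeline(cfg)
report
#> macrovol run: 40 cells (threshold 21; -0 small, -0 outliers)
#>  region n_cells solidity_mean solidity_sd volume_mean_um3 volume_sd_um3
#>     All      40     0.5838023   0.4224531          2425.6      395.9972
#>      ed      20     0.5829322   0.4286536          2386.4      399.8155
#>     vva      20     0.5846724   0.4272947          2464.8      398.4889
#>  radius_mean_um radius_sd_um sd_degenerate
#>        8.311293    0.4503216         FALSE
#>        8.265775    0.4582675         FALSE
#>        8.356810    0.4493122         FALSE
#> occupancy: ed = 0.1397, vva = 0.1455
```

Per-cell morphometrics:

```r
head(report$cells[, c("cell_id", "region", "morphology", "voxel_count",
                      "volume_um3", "solidity", "equiv_radius_um")])
#>   cell_id region morphology voxel_count volume_um3 solidity equiv_radius_um
#> 1       1     ed   ramified         259       2072    0.181            7.91
#> 2       2     ed   ramified         291       2328    0.167            8.22
#> 3       3     ed   ramified         310       2480    0.113            8.40
#> 4       4     ed   ramified         258       2064    0.196            7.91
#> 5       5     ed   ramified         249       1992    0.179            7.81
#> 6       6     ed   ramified         235       1880    0.223            7.66
```

The same machinery works on real data: load a marker stack with
`read_stack()` (multi-page TIFF with a JSON geometry sidecar, or NIfTI
with micrometre `pixdim`), a label map with `read_labels()`, and pass them
as `inputs = list(marker_channel = ..., roi_labels = ...)` to
`run_pipeline()`, or drive the individual steps (`extract_roi()`,
`dilate_roi()`, `mask_channel()`, `segment_cells()`, `measure_cells()`,
`summarize_regions()`, `occupancy()`, `fleiss_kappa()`).

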