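#!/usr/bin/env Rscript

# Step 2: segment macrophages from the simulated marker channel.
# Reads results/phantom/, applies per-ROI dilated masking and the
# threshold / 26-connectivity / size-filter chain, and writes the
# recovered cell label map and segmentation provenance under
# results/segmentation/.
#
# Usage: Rscript analysis/02_segment_cells.R

suppressPackageStartupMessages(library(macrovol))

marker <- read_stack(file.path("results", "phantom", "marker.tif"))
rois <- read_labels(file.path("results", "phantom", "truth_rois.nii.gz"),
                    marker$geometry)

# dilation radius that provably covers the full periductal cuff
dilation <- phantom_cuff_dilation_um(default_phantom_config())
combined <- array(FALSE, marker$geometry$shape)
for (r in sort(unname(rois$label_names))) {
  combined <- combined | dilate_roi(extract_roi(rois, r), dilation, marker$geometry)
}
masked <- mask_channel(marker, combined, roi_name = "ed+vva", dilation_um = dilation)
seg <- segment_cells(masked, segmentation_params())

out <- file.path("results", "segmentation")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write_labels(seg$cell_labels, file.path(out, "cells.nii.gz"))
utils::write.csv(
  data.frame(n_cells = seg$n_cells,
             threshold_used = seg$threshold_used,
             removed_small = seg$removed_small,
             removed_outliers = seg$removed_outliers,
             dilation_um = dilation),
  file.path(out, "provenance.csv"), row.names = FALSE)

cat(sprintf("segmented %d cells (threshold %d; -%d small, -%d outliers) -> %s\n",
            seg$n_cells, seg$threshold_used, seg$removed_small,
            seg$removed_outliers, out))
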