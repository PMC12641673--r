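#!/usr/bin/env Rscript

# Step 1: simulate the two-duct phantom stack with exact ground truth.
# Writes the marker/structure channels (TIFF), truth label maps (NIfTI)
# and truth tables (CSV) under results/phantom/.
#
# Usage: Rscript analysis/01_simulate_phantom.R [--seed <int>]

suppressPackageStartupMessages(library(macrovol))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[match("--seed", args) + 1L] else 1L)

pc <- default_phantom_config()
pc$seed <- seed
phantom <- generate_phantom(pc)
out <- file.path("results", "phantom")
write_phantom(phantom, out)

cat(sprintf("phantom seed %d: %d cells, %d x %d x %d voxels -> %s\n",
            seed, nrow(phantom$truth$per_cell),
            pc$shape[1], pc$shape[2], pc$shape[3], out))
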