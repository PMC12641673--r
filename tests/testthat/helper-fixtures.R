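# Shared fixtures for fast unit tests. The small phantom keeps one short
# duct and a handful of cells so module tests run in seconds; acceptance
# tests use the full default phantom.

small_phantom_config <- function(seed = 1L) {
  pc <- default_phantom_config()
  pc$shape <- c(56L, 96L, 64L)
  pc$regions <- list(list(name = "ed",
                          centerline_um = rbind(c(56, 16, 64), c(56, 176, 64)),
                          radius_um = 8))
  pc$cells_per_region <- list(ed = c(ameboid = 3L, ramified = 3L))
  pc$ramified_branch_len_um <- c(14, 24)
  pc$ramified_n_branches <- c(3L, 4L)
  pc$seed <- seed
  pc
}

small_pipeline_config <- function(seed = 1L, out_dir = tempfile("mvrun")) {
  cfg <- default_config()
  cfg$phantom <- small_phantom_config(seed)
  cfg$masking$dilation_um <- phantom_cuff_dilation_um(cfg$phantom)
  # the MAD fence is documented as unreliable on very small populations
  # (here 6 cells); module tests exercise the plumbing, the acceptance
  # suite exercises the fence on the full 40-cell phantom
  cfg$segmentation$outlier_rule <- "none"
  cfg$output_dir <- out_dir
  cfg$seed <- seed
  cfg
}

# memoized noise-free default-phantom pipeline run, shared by the
# end-to-end, determinism and plausibility acceptance tests
.mv_cache <- new.env(parent = emptyenv())
default_noise_free_run <- function() {
  if (is.null(.mv_cache$run)) {
    cfg <- default_config()
    cfg$masking$dilation_um <- phantom_cuff_dilation_um(cfg$phantom)
    cfg$output_dir <- tempfile("mvdefault")
    .mv_cache$run <- list(config = cfg, report = run_pipeline(cfg))
  }
  .mv_cache$run
}
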