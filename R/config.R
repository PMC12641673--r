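#' Default pipeline configuration
#'
#' Returns the full configuration with every default applied. Defaults
#' follow the published pipeline where it states them (26-connectivity
#' labeling, strict removal of objects under 100 voxels) and documented
#' package choices elsewhere (Otsu thresholding over in-mask voxels,
#' upper-tail median + 3 x scaled-MAD outlier rule, 12 um ROI dilation,
#' solidity 0.5 morphology cutoff).
#'
#' @return A nested list with sections `geometry`, `phantom`, `masking`,
#'   `segmentation`, `morphometry`, `agreement`, plus `output_dir` and
#'   `seed`.
#' @export
default_config <- function() {
  list(
    geometry = list(voxel_size_um = c(2, 2, 2)),
    phantom = default_phantom_config(),
    masking = list(
      rois = NULL,            # NULL = all ROIs in the label map
      dilation_um = 12,
      dilation_unit = "um"    # "um" or "voxel"
    ),
    segmentation = list(
      threshold_method = "otsu",  # "otsu" or "fixed"
      fixed_threshold = NULL,
      connectivity = 26,
      min_object_voxels = 100,
      min_object_unit = "voxel",  # "voxel" or "um3"
      outlier_rule = "upper_mad", # "upper_mad" or "none"
      mad_multiplier = 3.0
    ),
    morphometry = list(
      solidity_threshold = 0.5,
      max_distance_um = 12,       # region adjacency; defaults to masking dilation
      hull_space = "voxel"        # "voxel" or "physical"
    ),
    agreement = list(
      per_structure = FALSE
    ),
    output_dir = "results",
    seed = 1L
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys, fills defaults, and validates
#' value ranges. An empty file yields the full default configuration.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return A validated configuration list (see [default_config()]).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user, "config")
  }
  validate_config(cfg)
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) stop(sprintf("%s: expected a mapping", where))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("%s: unknown key(s): %s", where, paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(where, "$", k))
    } else {
      base[k] <- list(user[[k]])  # keeps explicit NULLs
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(length(geometry$voxel_size_um) == 3)
    if (any(geometry$voxel_size_um <= 0)) stop("geometry$voxel_size_um must be positive")
    if (masking$dilation_um < 0) stop("masking$dilation_um must be >= 0 (negative radius rejected)")
    if (!masking$dilation_unit %in% c("um", "voxel")) stop("masking$dilation_unit must be 'um' or 'voxel'")
    if (!segmentation$threshold_method %in% c("otsu", "fixed"))
      stop("segmentation$threshold_method must be 'otsu' or 'fixed'")
    if (segmentation$threshold_method == "fixed" && is.null(segmentation$fixed_threshold))
      stop("fixed_threshold is required when threshold_method = 'fixed'")
    if (!segmentation$connectivity %in% c(6, 18, 26))
      stop("segmentation$connectivity must be 6, 18 or 26")
    if (segmentation$min_object_voxels <= 0)
      stop("segmentation$min_object_voxels must be positive")
    if (!segmentation$outlier_rule %in% c("none", "upper_mad"))
      stop("segmentation$outlier_rule must be 'none' or 'upper_mad'")
    if (segmentation$mad_multiplier <= 0) stop("segmentation$mad_multiplier must be positive")
    if (morphometry$solidity_threshold <= 0 || morphometry$solidity_threshold >= 1)
      stop("morphometry$solidity_threshold must be in (0, 1)")
    if (morphometry$max_distance_um < 0) stop("morphometry$max_distance_um must be >= 0")
    if (!morphometry$hull_space %in% c("voxel", "physical"))
      stop("morphometry$hull_space must be 'voxel' or 'physical'")
  })
  if (!is.null(cfg$phantom)) validate_phantom_config(cfg$phantom)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
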