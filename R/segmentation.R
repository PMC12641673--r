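#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (computed over in-mask voxels only) or
#'   `"fixed"`.
#' @param fixed_threshold integer threshold, required iff `method = "fixed"`;
#'   foreground is `intensity >= fixed_threshold`.
#' @param connectivity 6, 18 or 26 (default 26: voxels sharing a face, edge
#'   or corner belong to the same object).
#' @param min_object_voxels strict small-object cutoff: objects with fewer
#'   voxels than this are removed (default 100).
#' @param outlier_rule `"upper_mad"` (default) removes objects whose voxel
#'   count exceeds `median + mad_multiplier * 1.4826 * MAD`; `"none"`
#'   disables the step.
#' @param mad_multiplier positive real, default 3.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                connectivity = 26L,
                                min_object_voxels = 100L,
                                outlier_rule = c("upper_mad", "none"),
                                mad_multiplier = 3.0) {
  threshold_method <- match.arg(threshold_method)
  outlier_rule <- match.arg(outlier_rule)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when threshold_method = 'fixed'")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (min_object_voxels < 1) stop("min_object_voxels must be positive")
  if (mad_multiplier <= 0) stop("mad_multiplier must be positive")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 connectivity = as.integer(connectivity),
                 min_object_voxels = as.integer(min_object_voxels),
                 outlier_rule = outlier_rule,
                 mad_multiplier = mad_multiplier),
            class = "segmentation_params")
}

#' Threshold a masked marker channel
#'
#' Otsu's threshold is computed over the in-mask (nonzero-support) voxels
#' only, because the masked-out zeros would otherwise dominate the
#' histogram. Foreground is `intensity >= threshold` within the mask.
#'
#' @param masked a `masked_channel` from [mask_channel()] (or any
#'   [intensity_volume()], in which case the whole stack is in-mask).
#' @param params a [segmentation_params()].
#' @return Logical 3D array with attribute `threshold_used`.
#' @export
threshold_channel <- function(masked, params = segmentation_params()) {
  vals <- masked$values
  mask <- if (!is.null(masked$mask)) masked$mask else array(TRUE, dim(vals))
  if (!any(mask)) stop("empty mask: no voxels to threshold")
  if (params$threshold_method == "fixed") {
    thr <- as.integer(params$fixed_threshold)
  } else {
    thr <- otsu_threshold(vals[mask])
  }
  fg <- array(FALSE, dim(vals))
  fg[mask] <- vals[mask] >= thr
  attr(fg, "threshold_used") <- thr
  fg
}

# Otsu's method on an integer sample: the returned integer threshold t
# maximizes between-class variance for the split {x < t} vs {x >= t}.
otsu_threshold <- function(x) {
  tab <- table(x)
  levels <- as.integer(names(tab))
  if (length(levels) < 2L) return(levels[1] + 1L)
  cnt <- as.numeric(tab)
  n <- sum(cnt)
  cum_n <- cumsum(cnt)
  cum_s <- cumsum(cnt * levels)
  total <- cum_s[length(cum_s)]
  # candidate thresholds: just above each level except the last
  w0 <- cum_n[-length(cum_n)]
  s0 <- cum_s[-length(cum_s)]
  w1 <- n - w0
  m0 <- s0 / w0
  m1 <- (total - s0) / w1
  between <- w0 * w1 * (m0 - m1)^2
  k <- which.max(between)
  levels[k] + 1L  # foreground = values >= this
}

#' Label connected components of a binary volume
#'
#' Maximal connected components under 6-, 18- or 26-connectivity. Labels are
#' assigned in scan order of each component's first voxel (first axis
#' fastest), so the labeling is deterministic.
#'
#' @param binary logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @param geometry a [stack_geometry()] for the output container; defaults
#'   to unit voxels.
#' @return A [label_volume()] with labels `1..M`.
#' @export
label_components <- function(binary, connectivity = 26L, geometry = NULL) {
  stopifnot(is.logical(binary), length(dim(binary)) == 3L)
  if (is.null(geometry)) geometry <- stack_geometry(c(1, 1, 1), dim(binary))
  lab <- .cc_label_cpp(as.vector(binary), dim(binary), as.integer(connectivity))
  label_volume(array(lab, dim(binary)), geometry)
}

#' Remove small objects from a labeled volume
#'
#' Objects with voxel count strictly below `min_object_voxels` are deleted;
#' surviving labels are recompacted to `1..M` preserving order.
#'
#' @param cells a [label_volume()].
#' @param min_object_voxels strict cutoff (an object of exactly this size is
#'   kept).
#' @return A [label_volume()]; attribute `removed_small` counts deletions.
#' @export
filter_small <- function(cells, min_object_voxels = 100L) {
  stopifnot(inherits(cells, "label_volume"))
  counts <- label_counts(cells$labels)
  keep <- counts >= min_object_voxels
  out <- relabel_keep(cells, keep)
  attr(out, "removed_small") <- sum(!keep)
  out
}

#' Remove large volume outliers from a labeled volume
#'
#' Under `rule = "upper_mad"`, objects whose voxel count exceeds
#' `median + mad_multiplier * 1.4826 * MAD` of the object counts are removed
#' (upper tail only, since segmentation artifacts are oversized fusions).
#' With fewer than 3 objects, or when the MAD is 0, nothing is removed and a
#' warning is raised.
#'
#' @param cells a [label_volume()].
#' @param rule `"upper_mad"` or `"none"`.
#' @param mad_multiplier positive multiplier, default 3.
#' @return A [label_volume()]; attribute `removed_outliers` counts deletions.
#' @export
filter_outliers <- function(cells, rule = c("upper_mad", "none"), mad_multiplier = 3.0) {
  stopifnot(inherits(cells, "label_volume"))
  rule <- match.arg(rule)
  counts <- label_counts(cells$labels)
  if (rule == "none" || length(counts) == 0L) {
    attr(cells, "removed_outliers") <- 0L
    return(cells)
  }
  if (length(counts) < 3L) {
    warning("fewer than 3 objects: outlier removal skipped")
    attr(cells, "removed_outliers") <- 0L
    return(cells)
  }
  med <- stats::median(counts)
  sigma <- stats::mad(counts)  # 1.4826 * median absolute deviation
  if (sigma == 0) {
    warning("zero MAD of object volumes: outlier removal skipped")
    attr(cells, "removed_outliers") <- 0L
    return(cells)
  }
  keep <- counts <= med + mad_multiplier * sigma
  out <- relabel_keep(cells, keep)
  attr(out, "removed_outliers") <- sum(!keep)
  out
}

label_counts <- function(arr) {
  m <- max(arr)
  if (m == 0L) return(integer(0))
  tabulate(arr[arr > 0L], nbins = m)
}

relabel_keep <- function(cells, keep) {
  m <- length(keep)
  map <- integer(m)
  map[keep] <- seq_len(sum(keep))
  arr <- cells$labels
  nz <- arr > 0L
  arr[nz] <- map[arr[nz]]
  old_names <- cells$label_names
  new_names <- NULL
  if (length(old_names)) {
    kept_old <- which(keep)
    nm <- old_names[as.character(kept_old)]
    nm <- nm[!is.na(nm)]
    if (length(nm)) new_names <- stats::setNames(unname(nm), as.character(map[kept_old]))
  }
  label_volume(arr, cells$geometry, new_names)
}

#' Segment cells from a masked marker channel
#'
#' The full object-extraction chain: threshold, connected-component labeling
#' at the chosen connectivity, strict small-object removal, then upper-tail
#' volume-outlier removal (in that order, so the outlier statistic is
#' computed on the size-filtered population).
#'
#' @param masked a `masked_channel` (or [intensity_volume()]).
#' @param params a [segmentation_params()].
#' @return A list of class `cell_label_result`: `cell_labels`
#'   ([label_volume()] with compact labels `1..M`), `removed_small`,
#'   `removed_outliers`, `threshold_used`, `n_cells`.
#' @export
segment_cells <- function(masked, params = segmentation_params()) {
  fg <- threshold_channel(masked, params)
  lab <- label_components(fg, params$connectivity, masked$geometry)
  lab <- filter_small(lab, params$min_object_voxels)
  removed_small <- attr(lab, "removed_small")
  lab2 <- filter_outliers(lab, params$outlier_rule, params$mad_multiplier)
  removed_outliers <- attr(lab2, "removed_outliers")
  structure(list(cell_labels = lab2,
                 removed_small = removed_small,
                 removed_outliers = removed_outliers,
                 threshold_used = attr(fg, "threshold_used"),
                 n_cells = max(lab2$labels)),
            class = "cell_label_result")
}
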