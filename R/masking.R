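#' Extract one structure's binary ROI from a label map
#'
#' @param labels a [label_volume()].
#' @param name structure name (must exist in `label_names`).
#' @return Logical 3D array, `TRUE` where the label map equals that
#'   structure's index.
#' @export
extract_roi <- function(labels, name) {
  stopifnot(inherits(labels, "label_volume"))
  hit <- which(labels$label_names == name)
  if (!length(hit))
    stop(sprintf("unknown ROI '%s'; available: %s", name,
                 paste(labels$label_names, collapse = ", ")))
  idx <- as.integer(names(labels$label_names)[hit[1]])
  mask <- labels$labels == idx
  if (!any(mask)) warning(sprintf("ROI '%s' has zero voxels", name))
  mask
}

#' Dilate a binary ROI by a physical radius
#'
#' Morphological dilation by a ball of physical radius `dilation_um`,
#' rasterized with the voxel-center rule and aware of anisotropic voxel
#' sizes: a voxel joins the dilated support iff its center lies within
#' `dilation_um` of some mask voxel center (implemented via an exact
#' anisotropic Euclidean distance transform). `dilation_um = 0` returns the
#' input unchanged.
#'
#' @param mask logical 3D array.
#' @param dilation_um dilation radius in um, >= 0. With
#'   `unit = "voxel"` the radius is in voxels of the smallest axis.
#' @param geometry a [stack_geometry()].
#' @param unit `"um"` (default) or `"voxel"`.
#' @return Logical 3D array (superset of the input support).
#' @export
dilate_roi <- function(mask, dilation_um, geometry, unit = c("um", "voxel")) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  unit <- match.arg(unit)
  if (dilation_um < 0) stop("dilation radius must be >= 0")
  if (unit == "voxel") dilation_um <- dilation_um * min(geometry$voxel_size_um)
  if (dilation_um == 0 || !any(mask)) return(mask)
  d2 <- .edt_sq_cpp(as.vector(mask), dim(mask), geometry$voxel_size_um)
  array(d2 <= dilation_um^2 + 1e-9, dim(mask))
}

#' Apply a binary mask to a marker channel
#'
#' Voxelwise product: intensities inside the mask are unchanged, everything
#' outside is set to 0, so downstream thresholding only sees the ROI
#' neighborhood.
#'
#' @param channel an [intensity_volume()].
#' @param dilated_mask logical array of the same shape.
#' @param roi_name name recorded on the output (for reports).
#' @param dilation_um dilation that produced the mask (metadata).
#' @return A `masked_channel`: an [intensity_volume()] with attributes
#'   `roi_name` and `dilation_um`.
#' @export
mask_channel <- function(channel, dilated_mask, roi_name = "roi", dilation_um = NA_real_) {
  stopifnot(inherits(channel, "intensity_volume"))
  if (!identical(dim(dilated_mask), dim(channel$values)))
    stop(sprintf("mask shape (%s) does not match channel shape (%s)",
                 paste(dim(dilated_mask), collapse = ","),
                 paste(dim(channel$values), collapse = ",")))
  vals <- channel$values
  vals[!dilated_mask] <- 0L
  out <- intensity_volume(vals, channel$geometry)
  out$mask <- dilated_mask
  out$roi_name <- roi_name
  out$dilation_um <- dilation_um
  class(out) <- c("masked_channel", class(out))
  out
}
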