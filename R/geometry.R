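#' Stack geometry: voxel sizes and shape
#'
#' Describes the sampling grid of a volumetric stack: per-axis voxel size in
#' micrometres and the array shape, both in `(z, y, x)` order. All physical
#' quantities in the package (volumes, distances, radii) are derived from
#' this object, so anisotropic stacks are handled everywhere.
#'
#' @param voxel_size_um numeric length-3, per-axis voxel size in um
#'   (z, y, x); all entries must be > 0.
#' @param shape integer length-3 array shape (z, y, x); all entries >= 1.
#' @return An object of class `stack_geometry` with elements
#'   `voxel_size_um`, `shape`, and the derived `voxel_volume_um3`.
#' @examples
#' g <- stack_geometry(c(2, 2, 2), c(8, 64, 64))
#' g$voxel_volume_um3  # 8
#' @export
stack_geometry <- function(voxel_size_um, shape) {
  voxel_size_um <- as.numeric(voxel_size_um)
  shape <- as.integer(shape)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("voxel_size_um must be 3 positive finite numbers (z, y, x)")
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be 3 integers >= 1 (z, y, x)")
  structure(
    list(voxel_size_um = voxel_size_um,
         shape = shape,
         voxel_volume_um3 = prod(voxel_size_um)),
    class = "stack_geometry"
  )
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf("stack_geometry: shape (z,y,x) = %s, voxel %s um, voxel volume %.4g um^3\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_um), collapse = " x "),
              x$voxel_volume_um3))
  invisible(x)
}

#' Convert a voxel count to physical volume
#'
#' @param count non-negative voxel count (vectorised).
#' @param geometry a [stack_geometry()].
#' @return Volume in cubic micrometres, `count * voxel_volume_um3` exactly.
#' @export
voxels_to_um3 <- function(count, geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (any(count < 0)) stop("voxel count must be non-negative")
  count * geometry$voxel_volume_um3
}

#' Intensity volume container
#'
#' A 3D array of non-negative integer intensities in `(z, y, x)` axis order
#' plus its [stack_geometry()]. Carrier for marker and structure channels.
#'
#' @param values 3D array of non-negative integers.
#' @param geometry a [stack_geometry()]; its shape must equal `dim(values)`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop(sprintf("array shape (%s) does not match geometry shape (%s)",
                 paste(dim(values), collapse = ","),
                 paste(geometry$shape, collapse = ",")))
  if (is.double(values)) {
    if (any(values != floor(values) | values < 0, na.rm = TRUE))
      stop("intensities must be non-negative integers")
    storage.mode(values) <- "integer"
  }
  if (!is.integer(values)) stop(sprintf("unsupported intensity dtype: %s", typeof(values)))
  if (anyNA(values)) stop("intensities contain NA")
  if (any(values < 0L)) stop("intensities must be non-negative")
  structure(list(values = values, geometry = geometry), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("intensity_volume: shape %s, range [%d, %d]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  print(x$geometry)
  invisible(x)
}

#' Integer label volume container
#'
#' A 3D array of non-negative integer labels (0 = background) in `(z, y, x)`
#' order, a [stack_geometry()], and a label-name table. Used for anatomical
#' ROIs, rater segmentations, and per-cell label maps.
#'
#' @param labels 3D array of non-negative integers.
#' @param geometry a [stack_geometry()] matching `dim(labels)`.
#' @param label_names named character vector mapping label index (as the
#'   name, e.g. `"1"`) to structure name. Missing entries for labels present
#'   in the array are synthesized as `label_<k>`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, geometry, label_names = NULL) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (!identical(as.integer(dim(labels)), geometry$shape))
    stop(sprintf("label shape (%s) does not match geometry shape (%s)",
                 paste(dim(labels), collapse = ","),
                 paste(geometry$shape, collapse = ",")))
  if (is.double(labels)) {
    if (any(labels != floor(labels), na.rm = TRUE))
      stop("labels must be integers (float-valued volume rejected)")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop(sprintf("unsupported label dtype: %s", typeof(labels)))
  if (anyNA(labels) || any(labels < 0L)) stop("labels must be non-negative integers")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (is.null(label_names)) label_names <- character(0)
  missing <- setdiff(as.character(present), names(label_names))
  if (length(missing)) {
    synth <- paste0("label_", missing)
    names(synth) <- missing
    label_names <- c(label_names, synth)
  }
  label_names <- label_names[order(as.integer(names(label_names)))]
  structure(list(labels = labels, geometry = geometry, label_names = label_names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: shape %s, %d label(s)\n",
              paste(dim(x$labels), collapse = "x"), length(x$label_names)))
  if (length(x$label_names))
    cat(paste0("  ", names(x$label_names), " -> ", x$label_names, collapse = "\n"), "\n")
  invisible(x)
}

# physical coordinates (um) of voxel centers for 1-based array indices;
# the center of voxel (1,1,1) sits at 0.5 * voxel_size on each axis.
voxel_centers_um <- function(idx, geometry) {
  sweep(idx - 0.5, 2, geometry$voxel_size_um, `*`)
}
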