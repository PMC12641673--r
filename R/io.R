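#' Read a volumetric stack (multi-page TIFF or NIfTI)
#'
#' TIFF stacks carry no voxel-size metadata, so geometry comes from a
#' `<path>.geometry.json` sidecar (written by [write_stack()]) or from
#' `geometry_override`; with neither, voxel size defaults to 1 um with a
#' warning. NIfTI geometry comes from `pixdim`; spatial units must be
#' micrometres (or unknown, taken as um) — a header declaring another unit
#' is rejected unless an override is supplied.
#'
#' @param path path to a `.tif`/`.tiff` multi-page file or `.nii`/`.nii.gz`.
#' @param geometry_override optional [stack_geometry()] or length-3 voxel
#'   size (z, y, x) in um that replaces file metadata.
#' @return An [intensity_volume()] in `(z, y, x)` axis order.
#' @export
read_stack <- function(path, geometry_override = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L && length(dim(pages[[1]])) == 2L && length(pages) == 1L) {
      # a single page is still a (1, y, x) volume; flag true 2D-only intent
      if (is.null(geometry_override) && !file.exists(paste0(path, ".geometry.json")))
        stop("2D-only image: a single-page TIFF without geometry metadata is not a volume")
    }
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("multi-sample (colour) TIFF pages are not supported")
    if (any(vapply(pages, is.double, logical(1))))
      stop("non-integer dtype in TIFF: double (expected 8/16-bit unsigned integers)")
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    arr <- array(0L, c(nz, ny, nx))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
    vs <- NULL
    sidecar <- paste0(path, ".geometry.json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      vs <- as.numeric(meta$voxel_size_um)
    }
    geom <- resolve_geometry(geometry_override, vs, c(nz, ny, nx),
                             warn_default = "TIFF has no geometry metadata; assuming 1 um voxels")
    return(intensity_volume(arr, geom))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 2L) stop("2D-only image: NIfTI volume has no third dimension")
    if (length(d) != 3L) stop(sprintf("expected a 3D NIfTI volume, got %d dimensions", length(d)))
    vals <- as.vector(img)
    if (is.double(vals) && any(vals != floor(vals)))
      stop(sprintf("non-integer dtype in NIfTI: %s with fractional values", typeof(vals)))
    hdr <- RNifti::niftiHeader(img)
    units <- bitwAnd(as.integer(hdr$xyzt_units), 7L)  # spatial unit code
    vs_xyz <- RNifti::pixdim(img)[1:3]
    vs <- NULL
    if (units %in% c(0L, 3L)) {
      vs <- rev(vs_xyz)  # (x,y,z) -> (z,y,x)
    } else if (is.null(geometry_override)) {
      stop(sprintf("NIfTI spatial units are not micrometres (unit code %d); pass geometry_override", units))
    }
    arr <- aperm(array(as.integer(round(vals)), d), c(3, 2, 1))
    geom <- resolve_geometry(geometry_override, vs, dim(arr))
    return(intensity_volume(arr, geom))
  }
  stop(sprintf("unsupported stack format: %s (use .tif/.tiff or .nii/.nii.gz)", path))
}

resolve_geometry <- function(override, file_voxel_size, shape, warn_default = NULL) {
  if (!is.null(override)) {
    if (inherits(override, "stack_geometry")) {
      if (!identical(override$shape, as.integer(shape)))
        stop(sprintf("override shape (%s) does not match file shape (%s)",
                     paste(override$shape, collapse = ","), paste(shape, collapse = ",")))
      return(override)
    }
    return(stack_geometry(override, shape))
  }
  if (!is.null(file_voxel_size)) return(stack_geometry(file_voxel_size, shape))
  if (!is.null(warn_default)) warning(warn_default)
  stack_geometry(c(1, 1, 1), shape)
}

#' Write a volumetric stack
#'
#' TIFF output is 8- or 16-bit unsigned multi-page, with a
#' `<path>.geometry.json` sidecar holding the voxel size so that
#' [read_stack()] round-trips geometry. NIfTI output stores voxel size in
#' `pixdim` with micrometre units. Integer values round-trip bit-exactly in
#' both dialects.
#'
#' @param vol an [intensity_volume()] (or a [label_volume()] for NIfTI).
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  if (inherits(vol, "label_volume")) {
    arr <- vol$labels; geom <- vol$geometry
  } else {
    stopifnot(inherits(vol, "intensity_volume"))
    arr <- vol$values; geom <- vol$geometry
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(arr)
    if (mx > 65535L) stop("TIFF output supports at most 16-bit values")
    bits <- if (mx > 255L) 16L else 8L
    denom <- if (bits == 16L) 65535 else 255
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
    jsonlite::write_json(list(voxel_size_um = geom$voxel_size_um, axis_order = "zyx"),
                         paste0(path, ".geometry.json"), auto_unbox = FALSE, digits = NA)
    return(invisible(path))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
    RNifti::pixdim(img) <- rev(geom$voxel_size_um)
    img <- RNifti::asNifti(img, reference = list(xyzt_units = 3L))
    dt <- if (max(arr) > 32767L || min(arr) < -32768L) "int32" else "int16"
    RNifti::writeNifti(img, path, datatype = dt)
    return(invisible(path))
  }
  stop(sprintf("unsupported stack format: %s", path))
}

#' Read an integer label map with optional name sidecar
#'
#' Labels are loaded from a NIfTI or TIFF file and validated against the
#' supplied geometry. Label names come from a plain-text sidecar
#' `<path>.labels.txt` with `index<TAB>name` lines (the ITK-SNAP label
#' description convention, reduced to its two essential columns); absent
#' entries are synthesized as `label_<k>`.
#'
#' @param path label map path (`.nii`, `.nii.gz`, `.tif`).
#' @param geometry the expected [stack_geometry()].
#' @return A [label_volume()].
#' @export
read_labels <- function(path, geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) stop("label map must be a 3D volume")
    vals <- as.vector(img)
    if (is.double(vals) && any(vals != floor(vals)))
      stop("float-valued label map rejected: labels must be integers")
    arr <- aperm(array(as.integer(round(vals)), d), c(3, 2, 1))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    vol <- read_stack(path, geometry_override = geometry)
    arr <- vol$values
  } else stop(sprintf("unsupported label format: %s", path))
  if (!identical(as.integer(dim(arr)), geometry$shape))
    stop(sprintf("label map shape (%s) does not match expected geometry shape (%s)",
                 paste(dim(arr), collapse = ","), paste(geometry$shape, collapse = ",")))
  label_names <- read_label_sidecar(paste0(path, ".labels.txt"))
  label_volume(arr, geometry, label_names)
}

read_label_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  idx <- vapply(parts, function(p) p[[1]], character(1))
  nm <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else NA_character_, character(1))
  if (anyNA(nm)) stop("malformed label sidecar: expected index<TAB>name lines")
  stats::setNames(nm, trimws(idx))
}

#' Write an integer label map plus name sidecar
#'
#' @param lab a [label_volume()].
#' @param path output path (`.nii`, `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  write_stack(lab, path)
  if (length(lab$label_names)) {
    writeLines(paste0(names(lab$label_names), "\t", lab$label_names),
               paste0(path, ".labels.txt"))
  }
  invisible(path)
}
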