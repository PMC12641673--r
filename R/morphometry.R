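#' Physical volume of a cell from its voxel count
#'
#' Volume is the voxel count scaled by the physical voxel volume, exactly.
#'
#' @param voxel_count integer >= 1.
#' @param geometry a [stack_geometry()].
#' @return Volume in cubic micrometres.
#' @export
cell_volume <- function(voxel_count, geometry) {
  if (any(voxel_count < 1)) stop("empty object: voxel_count must be >= 1")
  voxels_to_um3(voxel_count, geometry)
}

#' Rasterized convex-hull volume and solidity of a voxel set
#'
#' The hull volume Vh is the number of voxel centers lying inside or on the
#' convex hull of the cell's voxel centers (rasterized hull), and solidity
#' is Vm / Vh with Vm the cell's voxel count. With this convention any
#' rasterized convex shape — cuboid, digital ball, straight line — has
#' solidity exactly 1. Affinely degenerate voxel sets (single voxels, lines,
#' planes) have a hull that degenerates to their own rasterization, hence
#' solidity 1.
#'
#' By default the hull is computed in voxel space (index coordinates), the
#' convention used when a binarized stack is measured directly; under
#' anisotropic voxels a physical-space hull (centers in um) can differ, and
#' is available via `space = "physical"` for sensitivity analysis.
#'
#' @param vox integer matrix (n x 3) of 1-based (z,y,x) voxel indices.
#' @param space `"voxel"` (default) or `"physical"`.
#' @param geometry required for `space = "physical"`.
#' @param tol half-space tolerance for membership tests (default 1e-9;
#'   voxel-space tests on integer coordinates are exact regardless).
#' @return List with `hull_voxels`, `solidity`, `degenerate` (TRUE when the
#'   point set had affine rank < 3).
#' @export
hull_solidity <- function(vox, space = c("voxel", "physical"), geometry = NULL, tol = 1e-9) {
  space <- match.arg(space)
  vox <- as.matrix(vox)
  n <- nrow(vox)
  if (n < 1L) stop("empty voxel set")
  pts <- vox * 1.0
  if (space == "physical") {
    stopifnot(inherits(geometry, "stack_geometry"))
    pts <- sweep(pts, 2, geometry$voxel_size_um, `*`)
  }
  # query grid: every voxel center in the cell's bounding box
  rng <- lapply(1:3, function(a) min(vox[, a]):max(vox[, a]))
  qry <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]])) * 1.0
  if (space == "physical") qry <- sweep(qry, 2, geometry$voxel_size_um, `*`)
  cnt <- .hull_count_cpp(pts, qry, tol)
  if (cnt < 0) {
    # rank-deficient set: the hull rasterizes to the set itself
    return(list(hull_voxels = n, solidity = 1.0, degenerate = TRUE))
  }
  list(hull_voxels = cnt, solidity = n / cnt, degenerate = FALSE)
}

#' Equivalent-sphere radius from a physical volume
#'
#' @param volume_um3 volume in cubic micrometres, > 0.
#' @return Radius in um of the sphere with that volume, `(3 V / (4 pi))^(1/3)`.
#' @export
equiv_radius <- function(volume_um3) {
  if (any(volume_um3 <= 0)) stop("volume must be positive")
  (3 * volume_um3 / (4 * pi))^(1 / 3)
}

#' Classify morphology from solidity
#'
#' Ramified (branched) iff solidity < threshold; compact ameboid otherwise
#' (a cell exactly at the threshold is ameboid).
#'
#' @param solidity in (0, 1].
#' @param threshold cutoff in (0, 1), default 0.5.
#' @return Character vector, `"ameboid"` or `"ramified"`.
#' @export
classify_morphology <- function(solidity, threshold = 0.5) {
  if (any(solidity <= 0 | solidity > 1)) stop("solidity must be in (0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ifelse(solidity < threshold, "ramified", "ameboid")
}

#' Assign cells to their nearest region of interest
#'
#' For each ROI a physical (anisotropy-aware) Euclidean distance map is
#' computed; a cell's distance to a region is the minimum over its voxels.
#' The cell is assigned to the region with the smallest distance, with ties
#' broken by lexicographic region name, or `"unassigned"` when the minimum
#' exceeds `max_distance_um`.
#'
#' @param cell_labels a [label_volume()] of cells `1..M`.
#' @param roi_labels a [label_volume()] of regions.
#' @param max_distance_um adjacency cutoff in um.
#' @return Data frame: `cell_id`, `region`, `distance_um`.
#' @export
assign_region <- function(cell_labels, roi_labels, max_distance_um) {
  stopifnot(inherits(cell_labels, "label_volume"), inherits(roi_labels, "label_volume"))
  m <- max(cell_labels$labels)
  regions <- sort(unname(roi_labels$label_names))
  if (!length(regions) || !any(roi_labels$labels > 0L)) {
    warning("empty ROI map: all cells unassigned")
    return(data.frame(cell_id = seq_len(m), region = rep("unassigned", m),
                      distance_um = rep(NA_real_, m), stringsAsFactors = FALSE))
  }
  geom <- cell_labels$geometry
  nz <- which(cell_labels$labels > 0L)
  lab_nz <- cell_labels$labels[nz]
  dist_mat <- matrix(Inf, m, length(regions), dimnames = list(NULL, regions))
  for (r in regions) {
    mask <- extract_roi(roi_labels, r)
    if (!any(mask)) next
    d2 <- .edt_sq_cpp(as.vector(mask), geom$shape, geom$voxel_size_um)
    mins <- tapply(d2[nz], lab_nz, min)
    dist_mat[as.integer(names(mins)), r] <- sqrt(mins)
  }
  best <- apply(dist_mat, 1, function(row) {
    j <- which(row == min(row))[1]  # columns are sorted, so ties go lexicographic
    c(j, row[j])
  })
  region <- regions[best[1, ]]
  dist <- best[2, ]
  region[dist > max_distance_um + 1e-9] <- "unassigned"
  data.frame(cell_id = seq_len(m), region = region, distance_um = dist,
             stringsAsFactors = FALSE)
}

#' Fraction of an ROI occupied by segmented cells
#'
#' @param cell_labels a [label_volume()] (any nonzero voxel counts as cell).
#' @param roi_mask logical array of the same shape.
#' @param geometry unused for the ratio (both terms share the voxel volume);
#'   kept for interface symmetry.
#' @return Occupied fraction in `[0, 1]`.
#' @export
occupancy <- function(cell_labels, roi_mask, geometry = NULL) {
  arr <- if (inherits(cell_labels, "label_volume")) cell_labels$labels else cell_labels
  if (!identical(dim(arr), dim(roi_mask)))
    stop("cell labels and ROI mask shapes differ")
  denom <- sum(roi_mask)
  if (denom == 0) stop("empty ROI: occupancy undefined")
  sum(arr[roi_mask] > 0L) / denom
}

#' Per-cell morphometrics table
#'
#' For every labeled cell: voxel count, physical volume, rasterized hull
#' volume, solidity, equivalent-sphere radius, physical centroid, region
#' assignment and solidity-based morphology class.
#'
#' @param cell_labels a [label_volume()] of cells `1..M`.
#' @param roi_labels optional [label_volume()] of regions for assignment.
#' @param solidity_threshold morphology cutoff, default 0.5.
#' @param max_distance_um region adjacency cutoff, default 12.
#' @param hull_space `"voxel"` (default) or `"physical"`.
#' @return Data frame with columns `cell_id`, `region`, `morphology`,
#'   `voxel_count`, `volume_um3`, `hull_voxels`, `solidity`,
#'   `equiv_radius_um`, `centroid_z_um`, `centroid_y_um`, `centroid_x_um`.
#' @export
measure_cells <- function(cell_labels, roi_labels = NULL, solidity_threshold = 0.5,
                          max_distance_um = 12, hull_space = "voxel") {
  stopifnot(inherits(cell_labels, "label_volume"))
  geom <- cell_labels$geometry
  m <- max(cell_labels$labels)
  if (m == 0L) {
    return(data.frame(cell_id = integer(0), region = character(0), morphology = character(0),
                      voxel_count = integer(0), volume_um3 = numeric(0), hull_voxels = integer(0),
                      solidity = numeric(0), equiv_radius_um = numeric(0),
                      centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0), stringsAsFactors = FALSE))
  }
  nz <- which(cell_labels$labels > 0L)
  lab_nz <- cell_labels$labels[nz]
  shape <- geom$shape
  iz <- ((nz - 1L) %% shape[1]) + 1L
  iy <- (((nz - 1L) %/% shape[1]) %% shape[2]) + 1L
  ix <- ((nz - 1L) %/% (shape[1] * shape[2])) + 1L
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    sel <- lab_nz == k
    vox <- cbind(iz[sel], iy[sel], ix[sel])
    hs <- hull_solidity(vox, space = hull_space, geometry = geom)
    vc <- nrow(vox)
    vol <- cell_volume(vc, geom)
    ctr <- colMeans(voxel_centers_um(vox, geom))
    rows[[k]] <- data.frame(
      cell_id = k, voxel_count = vc, volume_um3 = vol,
      hull_voxels = hs$hull_voxels, solidity = hs$solidity,
      equiv_radius_um = equiv_radius(vol),
      centroid_z_um = ctr[1], centroid_y_um = ctr[2], centroid_x_um = ctr[3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$morphology <- classify_morphology(out$solidity, solidity_threshold)
  if (!is.null(roi_labels)) {
    asg <- assign_region(cell_labels, roi_labels, max_distance_um)
    out$region <- asg$region[match(out$cell_id, asg$cell_id)]
  } else {
    out$region <- "unassigned"
  }
  out[, c("cell_id", "region", "morphology", "voxel_count", "volume_um3",
          "hull_voxels", "solidity", "equiv_radius_um",
          "centroid_z_um", "centroid_y_um", "centroid_x_um")]
}

#' Per-region summary table
#'
#' One row per region plus an `"All"` row aggregating every cell once
#' (unassigned cells appear in their own row and in `"All"`). Mean and
#' sample standard deviation (n - 1 denominator) of solidity, volume and
#' equivalent radius; with a single cell the sd is reported as 0 with
#' `sd_degenerate = TRUE`.
#'
#' @param cells data frame from [measure_cells()].
#' @return Data frame with columns `region`, `n_cells`, `solidity_mean`,
#'   `solidity_sd`, `volume_mean_um3`, `volume_sd_um3`, `radius_mean_um`,
#'   `radius_sd_um`, `sd_degenerate`.
#' @export
summarize_regions <- function(cells) {
  one <- function(df, name) {
    n <- nrow(df)
    safe_sd <- function(x) if (n >= 2) stats::sd(x) else 0
    data.frame(region = name, n_cells = n,
               solidity_mean = if (n) mean(df$solidity) else NA_real_,
               solidity_sd = if (n) safe_sd(df$solidity) else NA_real_,
               volume_mean_um3 = if (n) mean(df$volume_um3) else NA_real_,
               volume_sd_um3 = if (n) safe_sd(df$volume_um3) else NA_real_,
               radius_mean_um = if (n) mean(df$equiv_radius_um) else NA_real_,
               radius_sd_um = if (n) safe_sd(df$equiv_radius_um) else NA_real_,
               sd_degenerate = n == 1L,
               stringsAsFactors = FALSE)
  }
  regions <- sort(unique(cells$region))
  rows <- c(list(one(cells, "All")),
            lapply(regions, function(r) one(cells[cells$region == r, , drop = FALSE], r)))
  do.call(rbind, rows)
}
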