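#' Default phantom configuration
#'
#' The phantom emulates the geometry the real stacks present: two straight
#' ducts ("ed", "vva") running in parallel through the volume, each wearing
#' a periductal cuff of cells, half compact ellipsoidal (ameboid) and half
#' thin-branched (ramified). Sizes bracket macrophage scale: ameboid
#' equivalent radii 8.2-9.2 um; ramified somata 5 um with 5-6 branches of
#' 20-34 um at 4 um thickness, giving rasterized solidities well below the
#' ameboid ones. Intensities are a two-level marker (background 20, cells
#' 200, 16-bit) with optional additive Gaussian noise (off by default; the
#' noisy study condition uses sd = 10% of the cell-background contrast).
#'
#' @return A `phantom_config` list; see [generate_phantom()].
#' @export
default_phantom_config <- function() {
  list(
    shape = c(64L, 224L, 96L),
    voxel_size_um = c(2, 2, 2),
    regions = list(
      list(name = "ed",
           centerline_um = rbind(c(64, 16, 60), c(64, 432, 60)),   # (z,y,x) um
           radius_um = 8),
      list(name = "vva",
           centerline_um = rbind(c(64, 16, 132), c(64, 432, 132)),
           radius_um = 8)
    ),
    cells_per_region = list(ed = c(ameboid = 10L, ramified = 10L),
                            vva = c(ameboid = 10L, ramified = 10L)),
    ameboid_equiv_radius_um = c(8.2, 9.2),
    ameboid_shape_factor = c(0.7, 1.3),
    ramified_n_branches = c(5L, 6L),
    ramified_branch_len_um = c(20, 34),
    ramified_thickness_um = 4,
    ramified_soma_radius_um = 5,
    shell_distance_um = 6,
    wall_thickness_um = 4,
    marker_intensity = 200L,
    structure_intensity = 120L,
    background_intensity = 20L,
    noise_sd = 0,
    min_cell_voxels = 120L,
    max_attempts = 1000L,
    seed = 1L
  )
}

validate_phantom_config <- function(pc) {
  stopifnot(length(pc$shape) == 3, length(pc$voxel_size_um) == 3)
  if (any(pc$voxel_size_um <= 0)) stop("phantom voxel sizes must be positive")
  for (r in pc$regions) {
    if (r$radius_um <= 0) stop("region tube radius must be positive")
    if (nrow(r$centerline_um) < 2) stop("centerline needs at least 2 control points")
  }
  counts <- unlist(pc$cells_per_region)
  if (any(counts < 0)) stop("cell counts must be >= 0")
  if (pc$marker_intensity <= pc$background_intensity)
    stop("marker_intensity must exceed background_intensity")
  if (any(c(pc$marker_intensity, pc$background_intensity, pc$structure_intensity) < 0))
    stop("intensities must be >= 0")
  if (pc$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(pc)
}

# linear indices (1-based) from an n x 3 matrix of 1-based (z,y,x) indices
lin_from_idx <- function(idx, shape) {
  as.vector(idx[, 1] + as.numeric(shape[1]) * (idx[, 2] - 1) +
              as.numeric(shape[1]) * shape[2] * (idx[, 3] - 1))
}

# grid of 1-based voxel indices within a physical bounding box (um)
grid_in_bbox <- function(lo_um, hi_um, geometry) {
  s <- geometry$voxel_size_um
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, ceiling(lo_um[a] / s[a] + 0.5))
    hi <- min(geometry$shape[a], floor(hi_um[a] / s[a] + 0.5))
    if (lo > hi) integer(0) else lo:hi
  })
  n <- vapply(rng, length, integer(1))
  if (any(n == 0L)) return(matrix(integer(0), 0, 3))
  cbind(rep(rng[[1]], times = n[2] * n[3]),
        rep(rep(rng[[2]], each = n[1]), times = n[3]),
        rep(rng[[3]], each = n[1] * n[2]))
}

#' Rasterize an ellipsoid (ameboid cell body)
#'
#' A voxel belongs to the cell iff its center lies inside or on the rotated
#' ellipsoid (voxel-center rule).
#'
#' @param center_um ellipsoid center, (z,y,x) um.
#' @param semi_axes_um length-3 semi-axes in um.
#' @param orientation 3x3 rotation matrix (columns = ellipsoid axes in
#'   (z,y,x) space), or `NULL` for axis-aligned.
#' @param geometry a [stack_geometry()].
#' @return Integer matrix (n x 3) of 1-based (z,y,x) voxel indices.
#' @export
rasterize_ameboid <- function(center_um, semi_axes_um, orientation = NULL, geometry) {
  if (any(semi_axes_um <= 0)) stop("semi-axes must be positive")
  if (is.null(orientation)) orientation <- diag(3)
  r <- max(semi_axes_um)
  idx <- grid_in_bbox(center_um - r - max(geometry$voxel_size_um),
                      center_um + r + max(geometry$voxel_size_um), geometry)
  if (nrow(idx) == 0L) stop("degenerate rasterization: ellipsoid misses every voxel center")
  d <- sweep(voxel_centers_um(idx, geometry), 2, center_um)
  local <- d %*% orientation                     # into ellipsoid frame
  q <- sweep(local, 2, semi_axes_um, `/`)
  inside <- rowSums(q^2) <= 1 + 1e-12
  if (!any(inside)) stop("degenerate rasterization: ellipsoid misses every voxel center")
  idx[inside, , drop = FALSE]
}

#' Rasterize a ramified cell (soma plus branched processes)
#'
#' A small spherical soma with `n_branches` tubular processes emanating in
#' random-walk directions; initial directions are drawn with a minimum
#' pairwise separation of 50 degrees so the processes radiate outward.
#' Each branch is a polyline of fixed-length steps
#' whose direction receives Gaussian angular jitter (`curl_sd`); a voxel
#' belongs to the cell iff its center lies within `thickness_um / 2` of the
#' sampled path (or within the soma radius). With default parameters the
#' rasterized convex-hull solidity of these cells is low (< 0.45), the
#' property that separates ramified from ameboid morphology.
#'
#' @param soma_center_um (z,y,x) um.
#' @param n_branches integer >= 2.
#' @param branch_len_um branch length in um (scalar or per branch); must be > 0.
#' @param thickness_um tube diameter in um.
#' @param geometry a [stack_geometry()].
#' @param directions optional n_branches x 3 matrix of fixed unit directions
#'   (disables the random walk; used for reproducible straight-arm shapes).
#' @param curl_sd per-step angular jitter (radians), default 0.15.
#' @param soma_radius_um soma radius, default `thickness_um / 2`.
#' @param seed optional integer seed applied locally for reproducibility.
#' @return Integer matrix (n x 3) of 1-based (z,y,x) voxel indices.
#' @export
rasterize_ramified <- function(soma_center_um, n_branches, branch_len_um, thickness_um,
                               geometry, directions = NULL, curl_sd = 0.15,
                               soma_radius_um = thickness_um / 2, seed = NULL) {
  if (n_branches < 2) stop("a ramified cell needs at least 2 branches")
  if (any(branch_len_um <= 0)) stop("zero-length branches are not allowed")
  if (thickness_um <= 0) stop("thickness must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lens <- rep_len(branch_len_um, n_branches)
  step <- min(geometry$voxel_size_um) / 2
  nsteps <- pmax(1L, ceiling(lens / step))
  if (is.null(directions)) {
    # processes radiate outward: initial directions are drawn with a minimum
    # pairwise separation of 50 degrees (rejection sampling), which prevents
    # all branches collapsing into one lobe and keeps the cell's rasterized
    # hull solidity low, the property that defines the ramified class
    init_dirs <- matrix(0, n_branches, 3)
    min_cos <- cos(50 * pi / 180)
    for (b in seq_len(n_branches)) {
      for (try in 1:200) {
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        if (b == 1L || all(init_dirs[seq_len(b - 1L), , drop = FALSE] %*% d < min_cos) ||
            try == 200L) break
      }
      init_dirs[b, ] <- d
    }
  } else {
    init_dirs <- directions / sqrt(rowSums(directions^2))
  }
  path <- matrix(0, 1L + sum(nsteps), 3)
  path[1, ] <- soma_center_um
  row <- 1L
  for (b in seq_len(n_branches)) {
    dir <- init_dirs[b, ]
    pos <- soma_center_um
    slen <- lens[b] / nsteps[b]
    for (k in seq_len(nsteps[b])) {
      if (is.null(directions) && curl_sd > 0) {
        dir <- dir + stats::rnorm(3, sd = curl_sd)
        dir <- dir / sqrt(sum(dir^2))
      }
      pos <- pos + slen * dir
      row <- row + 1L
      path[row, ] <- pos
    }
  }
  rad <- thickness_um / 2
  shape <- geometry$shape
  # per-sample local stamping: only voxels in the sample's own small
  # bounding box are distance-tested (fine path sampling makes the union
  # of balls a faithful tube rasterization)
  lins <- vector("list", nrow(path) + 1L)
  for (p in seq_len(nrow(path))) {
    r <- if (p == 1L) max(rad, soma_radius_um) else rad
    idx <- grid_in_bbox(path[p, ] - r, path[p, ] + r, geometry)
    if (nrow(idx) == 0L) next
    ctr <- voxel_centers_um(idx, geometry)
    d2 <- (ctr[, 1] - path[p, 1])^2 + (ctr[, 2] - path[p, 2])^2 + (ctr[, 3] - path[p, 3])^2
    keep <- d2 <= r^2 + 1e-12
    if (any(keep)) lins[[p]] <- lin_from_idx(idx[keep, , drop = FALSE], shape)
  }
  lin <- unique(unlist(lins))
  if (is.null(lin) || !length(lin))
    stop("degenerate rasterization: cell misses every voxel center")
  lin <- sort(lin)
  iz <- ((lin - 1) %% shape[1]) + 1
  iy <- (((lin - 1) %/% shape[1]) %% shape[2]) + 1
  ix <- ((lin - 1) %/% (shape[1] * shape[2])) + 1
  cbind(as.integer(iz), as.integer(iy), as.integer(ix), deparse.level = 0)
}

# voxel indices whose centers lie within radius_um of a polyline (um coords)
rasterize_tube <- function(centerline_um, radius_um, geometry) {
  lo <- apply(centerline_um, 2, min) - radius_um - max(geometry$voxel_size_um)
  hi <- apply(centerline_um, 2, max) + radius_um + max(geometry$voxel_size_um)
  idx <- grid_in_bbox(lo, hi, geometry)
  if (nrow(idx) == 0L) return(list(idx = idx, dist2 = numeric(0)))
  ctr <- voxel_centers_um(idx, geometry)
  best <- rep(Inf, nrow(idx))
  for (s in seq_len(nrow(centerline_um) - 1L)) {
    A <- centerline_um[s, ]; B <- centerline_um[s + 1L, ]
    AB <- B - A
    len2 <- sum(AB^2)
    pa <- sweep(ctr, 2, A)
    t <- pmin(pmax(as.vector(pa %*% AB) / len2, 0), 1)
    proj <- outer(t, AB)
    d2 <- rowSums((pa - proj)^2)
    best <- pmin(best, d2)
  }
  list(idx = idx, dist2 = best)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a two-channel phantom stack with exact ground truth
#'
#' Builds tubular duct/vessel ROIs, places non-overlapping (and non-adjacent,
#' so 26-connectivity labeling cannot merge them) ameboid and ramified cells
#' in a shell around each tube by rejection sampling, and renders a marker
#' channel (background + cells + optional Gaussian noise) and a decorative
#' structure channel (tube walls). Output is deterministic given
#' `config$seed`.
#'
#' @param config a phantom configuration, see [default_phantom_config()].
#' @return A list with `structure_channel` and `marker_channel`
#'   ([intensity_volume()]s) and `truth`: `cell_labels`, `roi_labels`
#'   ([label_volume()]s), `per_cell` (data.frame: cell_id, region,
#'   morphology, voxel_count, solidity), and `per_region` count table.
#' @export
generate_phantom <- function(config = default_phantom_config()) {
  pc <- utils::modifyList(default_phantom_config(), config)
  # structural sections are replaced wholly, not merged element-wise:
  # a config listing one region means one region, not "patch region 1"
  if (!is.null(config$regions)) pc$regions <- config$regions
  if (!is.null(config$cells_per_region)) pc$cells_per_region <- config$cells_per_region
  validate_phantom_config(pc)
  set.seed(pc$seed)
  geom <- stack_geometry(pc$voxel_size_um, pc$shape)
  shape <- geom$shape
  nvox <- prod(shape)

  roi_arr <- array(0L, shape)
  roi_names <- character(0)
  tubes <- list()
  for (i in seq_along(pc$regions)) {
    r <- pc$regions[[i]]
    tb <- rasterize_tube(r$centerline_um, r$radius_um, geom)
    inside <- tb$dist2 <= r$radius_um^2 + 1e-12
    roi_arr[lin_from_idx(tb$idx[inside, , drop = FALSE], shape)] <- i
    roi_names[as.character(i)] <- r$name
    tubes[[r$name]] <- list(spec = r, tb = tb)
  }

  # structure channel: tube walls
  struct_arr <- array(pc$background_intensity, shape)
  for (nm in names(tubes)) {
    t <- tubes[[nm]]
    wall <- t$tb$dist2 > t$spec$radius_um^2 &
      t$tb$dist2 <= (t$spec$radius_um + pc$wall_thickness_um)^2
    struct_arr[lin_from_idx(t$tb$idx[wall, , drop = FALSE], shape)] <- pc$structure_intensity
  }

  # cell placement
  occupied <- array(FALSE, shape)          # cell voxels
  blocked <- array(FALSE, shape)           # cell voxels dilated by 1 (26-adjacency guard)
  cell_arr <- array(0L, shape)
  per_cell <- list()
  cell_id <- 0L
  for (region in names(pc$cells_per_region)) {
    spec <- tubes[[region]]$spec
    counts <- pc$cells_per_region[[region]]
    plan <- c(rep("ameboid", counts[["ameboid"]]), rep("ramified", counts[["ramified"]]))
    for (morph in plan) {
      placed <- FALSE
      for (attempt in seq_len(pc$max_attempts)) {
        # random point on the centerline, random outward offset within the shell
        seg <- sample(nrow(spec$centerline_um) - 1L, 1L)
        t <- stats::runif(1)
        base <- spec$centerline_um[seg, ] * (1 - t) + spec$centerline_um[seg + 1L, ] * t
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        offset <- stats::runif(1, 0, pc$shell_distance_um)
        center <- base + (spec$radius_um + offset) * u
        vox <- tryCatch({
          if (morph == "ameboid") {
            req <- stats::runif(1, pc$ameboid_equiv_radius_um[1], pc$ameboid_equiv_radius_um[2])
            sf <- stats::runif(3, pc$ameboid_shape_factor[1], pc$ameboid_shape_factor[2])
            axes <- req * sf / prod(sf)^(1 / 3)
            rasterize_ameboid(center, axes, random_rotation(), geom)
          } else {
            nb <- sample(pc$ramified_n_branches[1]:pc$ramified_n_branches[2], 1L)
            lens <- stats::runif(nb, pc$ramified_branch_len_um[1], pc$ramified_branch_len_um[2])
            rasterize_ramified(center, nb, lens, pc$ramified_thickness_um, geom,
                               soma_radius_um = pc$ramified_soma_radius_um)
          }
        }, error = function(e) NULL)
        if (is.null(vox) || nrow(vox) < pc$min_cell_voxels) next
        # must fit fully inside the volume (bbox clipping would truncate it)
        ext <- extent_check(vox, center, morph, shape)
        if (!ext) next
        lin <- lin_from_idx(vox, shape)
        if (any(blocked[lin])) next
        cell_id <- cell_id + 1L
        cell_arr[lin] <- cell_id
        occupied[lin] <- TRUE
        blocked[lin_from_idx(dilate_idx_1(vox, shape), shape)] <- TRUE
        sol <- hull_solidity(vox)
        per_cell[[cell_id]] <- data.frame(
          cell_id = cell_id, region = region, morphology = morph,
          voxel_count = nrow(vox), solidity = sol$solidity,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place a %s cell near '%s' after %d attempts; use a larger volume or fewer cells",
                     morph, region, pc$max_attempts))
    }
  }
  per_cell <- if (length(per_cell)) do.call(rbind, per_cell) else
    data.frame(cell_id = integer(0), region = character(0), morphology = character(0),
               voxel_count = integer(0), solidity = numeric(0))

  # marker channel
  marker_arr <- array(as.numeric(pc$background_intensity), shape)
  marker_arr[occupied] <- pc$marker_intensity
  if (pc$noise_sd > 0) {
    marker_arr <- marker_arr + stats::rnorm(nvox, sd = pc$noise_sd)
  }
  marker_arr <- array(as.integer(pmin(pmax(round(marker_arr), 0), 65535)), shape)

  cell_names <- if (nrow(per_cell)) stats::setNames(sprintf("cell_%03d", per_cell$cell_id),
                                                    as.character(per_cell$cell_id)) else NULL
  per_region <- as.data.frame(table(region = factor(per_cell$region, levels = names(pc$cells_per_region)),
                                    morphology = factor(per_cell$morphology,
                                                        levels = c("ameboid", "ramified"))),
                              stringsAsFactors = FALSE)
  names(per_region)[3] <- "n_cells"

  list(
    structure_channel = intensity_volume(struct_arr, geom),
    marker_channel = intensity_volume(marker_arr, geom),
    truth = list(
      cell_labels = label_volume(cell_arr, geom, cell_names),
      roi_labels = label_volume(roi_arr, geom, roi_names),
      per_cell = per_cell,
      per_region = per_region,
      config = pc
    )
  )
}

# voxel set dilated by one voxel in every axis combination (26-neighborhood)
dilate_idx_1 <- function(vox, shape) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) sweep(vox, 2, -offs[k, ])))
  out <- out[out[, 1] >= 1 & out[, 1] <= shape[1] &
               out[, 2] >= 1 & out[, 2] <= shape[2] &
               out[, 3] >= 1 & out[, 3] <= shape[3], , drop = FALSE]
  unique(out)
}

# TRUE when the cell is plausibly un-truncated by the volume boundary:
# no voxel on the outermost layer of the array
extent_check <- function(vox, center, morph, shape) {
  !(any(vox[, 1] <= 1L) || any(vox[, 1] >= shape[1]) ||
      any(vox[, 2] <= 1L) || any(vox[, 2] >= shape[2]) ||
      any(vox[, 3] <= 1L) || any(vox[, 3] >= shape[3]))
}

#' Write a generated phantom to disk
#'
#' Two TIFF stacks (marker, structure), NIfTI truth label maps with name
#' sidecars, and CSV truth tables.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(phantom$marker_channel, file.path(dir, "marker.tif"))
  write_stack(phantom$structure_channel, file.path(dir, "structure.tif"))
  write_labels(phantom$truth$cell_labels, file.path(dir, "truth_cells.nii.gz"))
  write_labels(phantom$truth$roi_labels, file.path(dir, "truth_rois.nii.gz"))
  utils::write.csv(phantom$truth$per_cell, file.path(dir, "truth_per_cell.csv"), row.names = FALSE)
  utils::write.csv(phantom$truth$per_region, file.path(dir, "truth_per_region.csv"), row.names = FALSE)
  invisible(dir)
}

#' Dilation radius guaranteeing full cuff coverage for a phantom
#'
#' The mask dilation must reach every voxel of every generated cell for the
#' segmentation to see whole cells. The farthest a cell voxel can sit from
#' its region surface is the placement shell plus the cell's own maximal
#' extent (longest branch plus half its thickness for ramified cells; the
#' largest possible semi-axis for ameboid cells), which this helper computes
#' from the phantom configuration.
#'
#' @param pc a phantom configuration ([default_phantom_config()]).
#' @return Dilation radius in um.
#' @export
phantom_cuff_dilation_um <- function(pc = default_phantom_config()) {
  sf <- pc$ameboid_shape_factor
  # max semi-axis factor: one axis at the top factor, the others at the bottom
  axis_max <- pc$ameboid_equiv_radius_um[2] * sf[2] / (sf[2] * sf[1]^2)^(1 / 3)
  ram_reach <- pc$ramified_branch_len_um[2] + pc$ramified_thickness_um / 2
  pc$shell_distance_um + max(axis_max, ram_reach, pc$ramified_soma_radius_um)
}
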