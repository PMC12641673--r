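#' Match recovered cell labels against ground-truth labels
#'
#' Greedy maximum-overlap matching: each recovered object is paired with the
#' truth object sharing the most voxels. Used to validate end-to-end
#' parameter recovery on phantoms.
#'
#' @param truth_labels,recovered_labels [label_volume()]s of equal shape.
#' @return Data frame: `truth_id`, `recovered_id` (NA when missed),
#'   `truth_voxels`, `recovered_voxels`, `overlap_voxels`, `exact`
#'   (TRUE when the voxel sets are identical).
#' @export
match_cells <- function(truth_labels, recovered_labels) {
  ta <- truth_labels$labels
  ra <- recovered_labels$labels
  stopifnot(identical(dim(ta), dim(ra)))
  nt <- max(ta); nr <- max(ra)
  tc <- label_counts(ta); rc <- label_counts(ra)
  both <- which(ta > 0L & ra > 0L)
  ov <- if (length(both)) {
    tab <- table(truth = ta[both], recovered = ra[both])
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else data.frame(truth = character(0), recovered = character(0), Freq = integer(0))
  rows <- lapply(seq_len(nt), function(i) {
    sub <- ov[ov$truth == as.character(i) & ov$Freq > 0, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(truth_id = i, recovered_id = NA_integer_, truth_voxels = tc[i],
                        recovered_voxels = NA_integer_, overlap_voxels = 0L, exact = FALSE))
    }
    j <- as.integer(sub$recovered[which.max(sub$Freq)])
    o <- max(sub$Freq)
    data.frame(truth_id = i, recovered_id = j, truth_voxels = tc[i],
               recovered_voxels = rc[j], overlap_voxels = o,
               exact = o == tc[i] && o == rc[j])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_truth") <- nt
  attr(out, "n_recovered") <- nr
  out
}

# short stable content hash (FNV-1a over the serialized JSON) for provenance
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (FNV xors the octet into the low 8 bits);
    # kept in doubles because the running hash exceeds .Machine$integer.max
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

#' Run the full phantom-to-report pipeline
#'
#' Executes the stages in order: phantom generation (or loading of supplied
#' stacks), per-ROI masking with dilation, threshold + connected-component
#' segmentation with small-object and outlier filtering, per-cell
#' morphometry with region assignment, per-region summary and occupancy,
#' and (when rater maps are supplied or simulated) voxel-wise Fleiss kappa.
#' All intermediates and reports are written under `output_dir`; a rerun
#' with identical config and seed reproduces byte-identical CSV reports.
#'
#' @param config a configuration list from [load_config()] /
#'   [default_config()].
#' @param inputs optional list with pre-loaded `marker_channel`
#'   ([intensity_volume()]) and `roi_labels` ([label_volume()]); when absent
#'   the phantom section generates them.
#' @param rater_maps optional list of [label_volume()]s for agreement.
#' @param write_volumes write TIFF/NIfTI intermediates (default FALSE; the
#'   CSV/JSON report is always written).
#' @return A `run_report` list: `cells`, `summary`, `occupancy`,
#'   `segmentation` (per-ROI threshold and removal counts), `agreement`
#'   (or NULL), `truth` (phantom ground truth or NULL), `provenance`.
#' @export
run_pipeline <- function(config = default_config(), inputs = NULL, rater_maps = NULL,
                         write_volumes = FALSE) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(inputs)) {
    if (is.null(config$phantom))
      stop("stage 'inputs': no marker channel supplied and no phantom section present")
    pc <- config$phantom
    pc$seed <- config$seed
    ph <- generate_phantom(pc)
    marker <- ph$marker_channel
    roi_labels <- ph$truth$roi_labels
    truth <- ph$truth
    if (write_volumes) write_phantom(ph, file.path(out_dir, "phantom"))
  } else {
    if (is.null(inputs$marker_channel) || is.null(inputs$roi_labels))
      stop("stage 'inputs': inputs must contain marker_channel and roi_labels")
    marker <- inputs$marker_channel
    roi_labels <- inputs$roi_labels
  }
  geom <- marker$geometry
  rois <- config$masking$rois
  if (is.null(rois)) rois <- sort(unname(roi_labels$label_names))
  missing <- setdiff(rois, roi_labels$label_names)
  if (length(missing))
    stop(sprintf("stage 'masking': ROI(s) not present in label map: %s",
                 paste(missing, collapse = ", ")))

  sp <- segmentation_params(config$segmentation$threshold_method,
                            config$segmentation$fixed_threshold,
                            config$segmentation$connectivity,
                            config$segmentation$min_object_voxels,
                            config$segmentation$outlier_rule,
                            config$segmentation$mad_multiplier)

  # one combined mask over the requested ROIs, then one segmentation pass,
  # so a cell sitting between two ROIs is segmented once and assigned once
  combined <- array(FALSE, geom$shape)
  roi_masks <- list()
  for (r in rois) {
    m <- extract_roi(roi_labels, r)
    roi_masks[[r]] <- m
    combined <- combined | dilate_roi(m, config$masking$dilation_um, geom,
                                      unit = config$masking$dilation_unit)
  }
  masked <- mask_channel(marker, combined, roi_name = paste(rois, collapse = "+"),
                         dilation_um = config$masking$dilation_um)
  seg <- segment_cells(masked, sp)
  cells <- measure_cells(seg$cell_labels, roi_labels,
                         solidity_threshold = config$morphometry$solidity_threshold,
                         max_distance_um = config$morphometry$max_distance_um,
                         hull_space = config$morphometry$hull_space)
  summary_tab <- summarize_regions(cells)
  occ <- vapply(rois, function(r) occupancy(seg$cell_labels, roi_masks[[r]], geom), numeric(1))

  agreement <- NULL
  if (!is.null(rater_maps)) {
    agreement <- list(
      overall = fleiss_kappa_maps(rater_maps),
      per_structure = if (isTRUE(config$agreement$per_structure))
        per_structure_kappa(rater_maps) else NULL
    )
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("macrovol")),
    seed = config$seed,
    config_hash = config_hash(config),
    threshold_used = seg$threshold_used,
    removed_small = seg$removed_small,
    removed_outliers = seg$removed_outliers,
    dilation_um = config$masking$dilation_um,
    solidity_threshold = config$morphometry$solidity_threshold
  )

  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(summary_tab, file.path(out_dir, "region_summary.csv"), row.names = FALSE)
  report_json <- list(
    provenance = provenance,
    n_cells = seg$n_cells,
    occupancy = as.list(occ),
    kappa = if (!is.null(agreement)) agreement$overall$kappa else NULL
  )
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (write_volumes) {
    write_labels(seg$cell_labels, file.path(out_dir, "cells.nii.gz"))
  }

  structure(list(cells = cells, summary = summary_tab, occupancy = occ,
                 segmentation = seg, agreement = agreement, truth = truth,
                 provenance = provenance),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("macrovol run: %d cells (threshold %d; -%d small, -%d outliers)\n",
              x$segmentation$n_cells, x$provenance$threshold_used,
              x$provenance$removed_small, x$provenance$removed_outliers))
  print(x$summary, row.names = FALSE)
  cat("occupancy:", paste(sprintf("%s = %.4f", names(x$occupancy), x$occupancy),
                          collapse = ", "), "\n")
  if (!is.null(x$agreement))
    cat(sprintf("Fleiss kappa (overall): %.4f\n", x$agreement$overall$kappa))
  invisible(x)
}
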