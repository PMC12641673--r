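test_that("volumes and equivalent radii invert exactly", {
  g <- stack_geometry(c(5, 0.65, 0.65), c(4, 4, 4))
  expect_equal(cell_volume(10, g), 10 * 5 * 0.65 * 0.65)
  expect_error(cell_volume(0, g), "empty")
  r <- 7.3
  expect_equal(equiv_radius(4 / 3 * pi * r^3), r)
  expect_error(equiv_radius(0), "positive")
})

test_that("degenerate voxel sets (points, lines, planes) have solidity 1", {
  expect_equal(hull_solidity(rbind(c(3L, 3L, 3L)))$solidity, 1)
  line <- cbind(1:9, rep(2L, 9), rep(2L, 9))
  hs <- hull_solidity(line)
  expect_equal(hs$solidity, 1)
  expect_true(hs$degenerate)
  plane <- as.matrix(expand.grid(1:4, 1:5, 3L))
  expect_true(hull_solidity(plane)$degenerate)
})

test_that("voxel-space and physical-space hulls agree under isotropy", {
  set.seed(21)
  vox <- unique(matrix(sample.int(7L, 45, replace = TRUE), ncol = 3))
  g <- stack_geometry(c(2, 2, 2), c(8, 8, 8))
  a <- hull_solidity(vox, "voxel")
  b <- hull_solidity(vox, "physical", geometry = g)
  expect_equal(a$hull_voxels, b$hull_voxels)
  expect_equal(a$solidity, b$solidity)
})

test_that("morphology classification is strict at the threshold", {
  expect_identical(classify_morphology(c(0.49, 0.5, 0.51)),
                   c("ramified", "ameboid", "ameboid"))
  expect_identical(classify_morphology(0.3, threshold = 0.25), "ameboid")
  expect_error(classify_morphology(0), "\\(0, 1\\]")
  expect_error(classify_morphology(1.2), "\\(0, 1\\]")
  expect_error(classify_morphology(0.5, threshold = 1), "\\(0, 1\\)")
})

region_fixture <- function() {
  g <- stack_geometry(c(2, 2, 2), c(8, 20, 8))
  roi <- array(0L, c(8, 20, 8))
  roi[4, 3, 4] <- 1L   # "ed" at y-index 3
  roi[4, 17, 4] <- 2L  # "vva" at y-index 17
  roi_lv <- label_volume(roi, g, stats::setNames(c("ed", "vva"), c("1", "2")))
  list(g = g, roi = roi_lv)
}

test_that("cells are assigned to the nearest region with a distance cutoff", {
  fx <- region_fixture()
  cells <- array(0L, c(8, 20, 8))
  cells[4, 4, 4] <- 1L    # 2 um from ed
  cells[4, 15, 4] <- 2L   # 4 um from vva
  cells[1, 10, 1] <- 3L   # far from both
  cl <- label_volume(cells, fx$g)
  asg <- assign_region(cl, fx$roi, max_distance_um = 8)
  expect_identical(asg$region, c("ed", "vva", "unassigned"))
  expect_equal(asg$distance_um[1:2], c(2, 4))
})

test_that("equidistant assignments break ties by region name", {
  fx <- region_fixture()
  cells <- array(0L, c(8, 20, 8))
  cells[4, 10, 4] <- 1L  # exactly 14 um from both seeds
  cl <- label_volume(cells, fx$g)
  asg <- assign_region(cl, fx$roi, max_distance_um = 20)
  expect_identical(asg$region, "ed")
})

test_that("an empty region map leaves every cell unassigned with a warning", {
  g <- stack_geometry(c(1, 1, 1), c(4, 4, 4))
  cells <- array(0L, c(4, 4, 4)); cells[2, 2, 2] <- 1L
  roi <- label_volume(array(0L, c(4, 4, 4)), g)
  expect_warning(asg <- assign_region(label_volume(cells, g), roi, 10), "empty ROI")
  expect_identical(asg$region, "unassigned")
})

test_that("occupancy is the exact in-ROI cell fraction", {
  g <- stack_geometry(c(1, 1, 1), c(4, 4, 4))
  cells <- array(0L, c(4, 4, 4)); cells[1:6] <- 1L
  roi <- array(FALSE, c(4, 4, 4)); roi[4:11] <- TRUE  # overlap = voxels 4:6
  expect_equal(occupancy(label_volume(cells, g), roi), 3 / 8)
  expect_error(occupancy(label_volume(cells, g), array(FALSE, c(4, 4, 4))), "empty ROI")
  expect_error(occupancy(label_volume(cells, g), array(TRUE, c(2, 2, 2))), "shape")
})

test_that("per-cell measurements report exact volumes and centroids", {
  g <- stack_geometry(c(2, 3, 4), c(6, 6, 6))
  cells <- array(0L, c(6, 6, 6))
  cells[2:3, 2:4, 2:3] <- 1L  # 2 x 3 x 2 cuboid
  tab <- measure_cells(label_volume(cells, g))
  expect_identical(tab$voxel_count, 12L)
  expect_equal(tab$volume_um3, 12 * 2 * 3 * 4)
  expect_equal(tab$solidity, 1)        # rasterized convex shape
  expect_identical(tab$hull_voxels, 12L)
  expect_identical(tab$morphology, "ameboid")
  # centroid of index ranges (2:3, 2:4, 2:3) at voxel sizes (2,3,4)
  expect_equal(c(tab$centroid_z_um, tab$centroid_y_um, tab$centroid_x_um),
               c(2.5 * 2 - 1, 3 * 3 - 1.5, 2.5 * 4 - 2))
  expect_identical(nrow(measure_cells(label_volume(array(0L, c(6, 6, 6)), g))), 0L)
})

test_that("region summaries aggregate all cells once and flag degenerate sds", {
  cells <- data.frame(
    region = c("ed", "ed", "vva"),
    solidity = c(0.9, 0.7, 0.3),
    volume_um3 = c(100, 200, 400),
    equiv_radius_um = c(3, 4, 5))
  s <- summarize_regions(cells)
  expect_identical(s$region, c("All", "ed", "vva"))
  expect_identical(s$n_cells, c(3L, 2L, 1L))
  expect_equal(s$solidity_mean[1], mean(cells$solidity))
  expect_equal(s$volume_sd_um3[2], stats::sd(c(100, 200)))
  expect_equal(s$volume_sd_um3[3], 0)
  expect_identical(s$sd_degenerate, c(FALSE, FALSE, TRUE))
})
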