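test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(small_phantom_config(3))
  b <- generate_phantom(small_phantom_config(3))
  c <- generate_phantom(small_phantom_config(4))
  expect_identical(a$marker_channel$values, b$marker_channel$values)
  expect_identical(a$truth$cell_labels$labels, b$truth$cell_labels$labels)
  expect_false(identical(a$marker_channel$values, c$marker_channel$values))
})

test_that("phantom ground truth is internally consistent", {
  ph <- generate_phantom(small_phantom_config(2))
  tr <- ph$truth
  n <- nrow(tr$per_cell)
  expect_identical(sort(unique(as.vector(tr$cell_labels$labels))), c(0L, seq_len(n)))
  counts <- tabulate(tr$cell_labels$labels[tr$cell_labels$labels > 0L], nbins = n)
  expect_identical(counts, tr$per_cell$voxel_count)
  expect_true(all(counts >= tr$config$min_cell_voxels))
  expect_equal(sum(tr$per_region$n_cells), n)
  # marker channel is exactly two-level when noise is off
  vals <- ph$marker_channel$values
  expect_setequal(unique(as.vector(vals)), c(20L, 200L))
  expect_true(all(vals[tr$cell_labels$labels > 0L] == 200L))
  expect_true(all(vals[tr$cell_labels$labels == 0L] == 20L))
})

test_that("placed cells are pairwise non-adjacent at 26-connectivity", {
  ph <- generate_phantom(small_phantom_config(5))
  fg <- ph$truth$cell_labels$labels > 0L
  lab <- label_components(fg, 26L)
  expect_identical(max(lab$labels), nrow(ph$truth$per_cell))
})

test_that("region label maps are disjoint tubes with the requested names", {
  ph <- generate_phantom(default_phantom_config())
  roi <- ph$truth$roi_labels
  expect_setequal(unname(roi$label_names), c("ed", "vva"))
  m1 <- extract_roi(roi, "ed"); m2 <- extract_roi(roi, "vva")
  expect_false(any(m1 & m2))
  expect_gt(sum(m1), 0); expect_gt(sum(m2), 0)
  # straight tube of radius 8 um: every in-tube voxel center is within 8 um
  # of the centerline x=60, z=64 (um)
  idx <- which(m1, arr.ind = TRUE)
  ctr <- macrovol:::voxel_centers_um(idx, roi$geometry)
  d2 <- (ctr[, 1] - 64)^2 + (ctr[, 3] - 60)^2
  expect_true(all(d2 <= 8^2 + 1e-9))
})

test_that("ellipsoid rasterization matches the lattice-ball oracle for spheres", {
  g <- stack_geometry(c(2, 2, 2), c(24, 24, 24))
  ctr <- c(23, 23, 23)  # on a voxel center: (12 - 0.5) * 2 = 23
  for (r in c(5, 8.4, 11)) {
    vox <- rasterize_ameboid(ctr, c(r, r, r), NULL, g)
    expect_identical(nrow(vox), oracle_ball_count(r + 1e-9, c(2, 2, 2)))
  }
  expect_error(rasterize_ameboid(ctr, c(0, 1, 1), NULL, g), "positive")
})

test_that("ramified rasterization with fixed directions is deterministic and validates inputs", {
  g <- stack_geometry(c(2, 2, 2), c(40, 40, 40))
  dirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0))
  a <- rasterize_ramified(c(40, 40, 40), 3, 20, 4, g, directions = dirs)
  b <- rasterize_ramified(c(40, 40, 40), 3, 20, 4, g, directions = dirs)
  expect_identical(a, b)
  # straight arms lie inside the union of three tubes around the soma
  expect_error(rasterize_ramified(c(40, 40, 40), 1, 20, 4, g), "at least 2")
  expect_error(rasterize_ramified(c(40, 40, 40), 3, 0, 4, g), "[Zz]ero-length")
  expect_error(rasterize_ramified(c(40, 40, 40), 3, 20, -1, g), "positive")
})

test_that("the cuff dilation bound covers every generated cell voxel", {
  pc <- small_phantom_config(4)
  ph <- generate_phantom(pc)
  geom <- ph$truth$roi_labels$geometry
  dil <- dilate_roi(extract_roi(ph$truth$roi_labels, "ed"),
                    phantom_cuff_dilation_um(pc), geom)
  expect_true(all(dil[ph$truth$cell_labels$labels > 0L]))
})

test_that("phantom configs with impossible geometry fail loudly", {
  pc <- small_phantom_config()
  pc$marker_intensity <- 10L  # below background
  expect_error(generate_phantom(pc), "exceed")
  pc <- small_phantom_config()
  pc$noise_sd <- -1
  expect_error(generate_phantom(pc), "noise_sd")
  # a volume far too small to fit any cell must stop, not loop forever
  pc <- small_phantom_config()
  pc$shape <- c(8L, 16L, 8L)
  pc$max_attempts <- 25L
  expect_error(generate_phantom(pc), "could not place")
})

test_that("phantom stacks can be written and re-read losslessly", {
  ph <- generate_phantom(small_phantom_config(6))
  dir <- tempfile("phantomio")
  write_phantom(ph, dir)
  marker <- read_stack(file.path(dir, "marker.tif"))
  expect_identical(marker$values, ph$marker_channel$values)
  expect_equal(marker$geometry$voxel_size_um, ph$marker_channel$geometry$voxel_size_um)
  roi <- read_labels(file.path(dir, "truth_rois.nii.gz"), marker$geometry)
  expect_identical(roi$labels, ph$truth$roi_labels$labels)
  expect_setequal(unname(roi$label_names), unname(ph$truth$roi_labels$label_names))
})
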