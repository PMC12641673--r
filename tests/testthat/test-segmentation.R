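toy_volume <- function(vals, voxel = c(1, 1, 1)) {
  g <- stack_geometry(voxel, dim(vals))
  intensity_volume(vals, g)
}

test_that("Otsu thresholding separates a well-contrasted bimodal stack", {
  set.seed(3)
  arr <- array(20L, c(8, 8, 8))
  arr[3:5, 3:5, 3:5] <- 200L
  fg <- threshold_channel(toy_volume(arr))
  expect_identical(fg, array(arr == 200L, dim(arr)), ignore_attr = TRUE)
  thr <- attr(fg, "threshold_used")
  expect_true(thr > 20 && thr <= 200)
})

test_that("thresholding a masked channel uses in-mask voxels only", {
  # a large very bright out-of-mask slab would drag a global Otsu upward
  # past the in-mask foreground; the in-mask threshold must ignore it
  arr <- array(10L, c(10, 10, 10))
  arr[1:2, , ] <- 5000L              # irrelevant bright slab
  arr[6:7, 6:7, 6:7] <- 80L          # true in-mask foreground
  vol <- toy_volume(arr)
  mask <- array(FALSE, dim(arr)); mask[4:9, 4:9, 4:9] <- TRUE
  mc <- mask_channel(vol, mask)
  fg <- threshold_channel(mc)
  expect_identical(which(fg), which(arr == 80L))
  # foreground is restricted to the mask by construction
  expect_false(any(fg & !mask))
})

test_that("a fixed threshold means foreground = intensity >= threshold", {
  arr <- array(c(9L, 10L, 11L, 12L), c(4, 1, 1))
  vol <- toy_volume(arr)
  fg <- threshold_channel(vol, segmentation_params("fixed", fixed_threshold = 11))
  expect_identical(as.vector(fg), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(segmentation_params("fixed"), "fixed_threshold")
})

test_that("an empty mask cannot be thresholded", {
  vol <- toy_volume(array(1L, c(2, 2, 2)))
  mc <- suppressWarnings(mask_channel(vol, array(FALSE, c(2, 2, 2))))
  expect_error(threshold_channel(mc), "empty mask")
})

test_that("component labels are deterministic and connectivity-faithful", {
  b <- array(FALSE, c(4, 4, 4))
  b[1, 1, 1] <- TRUE; b[2, 2, 1] <- TRUE   # edge-touching in (z,y): 18 yes, 6 no
  expect_identical(max(label_components(b, 6L)$labels), 2L)
  expect_identical(max(label_components(b, 18L)$labels), 1L)
  expect_identical(max(label_components(b, 26L)$labels), 1L)
  # labels follow scan order of the first voxel of each component
  b2 <- array(FALSE, c(4, 4, 4))
  b2[4, 4, 4] <- TRUE; b2[1, 1, 1] <- TRUE
  lab <- label_components(b2, 26L)$labels
  expect_identical(lab[1, 1, 1], 1L)
  expect_identical(lab[4, 4, 4], 2L)
  expect_error(label_components(b, 10L), "6, 18 or 26")
})

test_that("small-object removal is strict and recompacts labels in order", {
  g <- stack_geometry(c(1, 1, 1), c(6, 30, 30))
  arr <- array(0L, c(6, 30, 30))
  arr[1, 1, 1:4] <- 1L       # 4 voxels: removed at cutoff 5
  arr[3, 1:5, 1] <- 2L       # 5 voxels: kept (strict <)
  arr[5, 1:9, 1] <- 3L       # 9 voxels: kept
  lv <- label_volume(arr, g)
  out <- filter_small(lv, 5L)
  expect_identical(attr(out, "removed_small"), 1L)
  expect_identical(max(out$labels), 2L)
  expect_identical(unique(as.vector(out$labels[arr == 2L])), 1L)
  expect_identical(unique(as.vector(out$labels[arr == 3L])), 2L)
})

test_that("outlier removal warns and does nothing on degenerate populations", {
  g <- stack_geometry(c(1, 1, 1), c(4, 12, 12))
  arr <- array(0L, c(4, 12, 12))
  arr[1, 1:5, 1] <- 1L; arr[3, 1:9, 1] <- 2L
  lv <- label_volume(arr, g)
  expect_warning(out <- filter_outliers(lv), "fewer than 3")
  expect_identical(attr(out, "removed_outliers"), 0L)
  # three objects of identical size: MAD is zero
  arr2 <- array(0L, c(4, 12, 12))
  arr2[1, 1:5, 1] <- 1L; arr2[2, 1:5, 3] <- 2L; arr2[4, 1:5, 5] <- 3L
  expect_warning(out2 <- filter_outliers(label_volume(arr2, g)), "zero MAD")
  expect_identical(attr(out2, "removed_outliers"), 0L)
  # rule "none" touches nothing
  out3 <- filter_outliers(lv, rule = "none")
  expect_identical(out3$labels, lv$labels)
})

test_that("segment_cells chains threshold, labeling and both filters", {
  arr <- array(20L, c(8, 20, 8))
  arr[3:5, 2:4, 3:5] <- 200L    # 27 voxels, kept
  arr[3:5, 8:10, 3:5] <- 200L   # 27 voxels, kept
  arr[7, 14, 7] <- 200L         # 1 voxel, removed as small
  vol <- toy_volume(arr)
  expect_warning(res <- segment_cells(vol, segmentation_params(min_object_voxels = 10L)),
                 "fewer than 3 objects")
  expect_s3_class(res, "cell_label_result")
  expect_identical(res$n_cells, 2L)
  expect_identical(res$removed_small, 1L)
  expect_true(res$threshold_used > 20)
})
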