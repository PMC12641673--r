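test_that("stack geometry validates voxel sizes and shape", {
  g <- stack_geometry(c(5, 0.65, 0.65), c(10, 20, 30))
  expect_s3_class(g, "stack_geometry")
  expect_identical(g$shape, c(10L, 20L, 30L))
  expect_equal(voxels_to_um3(1, g), 5 * 0.65 * 0.65)
  expect_error(stack_geometry(c(-1, 1, 1), c(2, 2, 2)))
  expect_error(stack_geometry(c(1, 1), c(2, 2, 2)))
})

test_that("intensity volumes accept integral values and reject others", {
  g <- stack_geometry(c(1, 1, 1), c(2, 2, 2))
  v <- intensity_volume(array(0:7, c(2, 2, 2)), g)
  expect_type(v$values, "integer")
  whole <- array(as.double(0:7), c(2, 2, 2))
  expect_type(intensity_volume(whole, g)$values, "integer")
  expect_error(intensity_volume(array(0.5, c(2, 2, 2)), g), "non-negative integers")
  expect_error(intensity_volume(array(-1L, c(2, 2, 2)), g))
  expect_error(intensity_volume(array(NA_integer_, c(2, 2, 2)), g))
})

test_that("label volumes synthesize names and reject float labels", {
  g <- stack_geometry(c(1, 1, 1), c(2, 2, 2))
  arr <- array(0L, c(2, 2, 2)); arr[1] <- 2L
  lv <- label_volume(arr, g)
  expect_true("label_2" %in% lv$label_names)
  expect_error(label_volume(array(1.5, c(2, 2, 2)), g), "integer|float")
})

test_that("voxel centers follow the half-offset convention", {
  g <- stack_geometry(c(2, 3, 4), c(5, 5, 5))
  ctr <- macrovol:::voxel_centers_um(rbind(c(1L, 1L, 1L), c(2L, 3L, 4L)), g)
  expect_equal(ctr[1, ], c(1, 1.5, 2))
  expect_equal(ctr[2, ], c(3, 7.5, 14))
})

test_that("TIFF stacks round-trip values and geometry via the sidecar", {
  g <- stack_geometry(c(5, 0.65, 0.65), c(4, 6, 5))
  set.seed(7)
  arr <- array(sample.int(60000L, 4 * 6 * 5, replace = TRUE), c(4, 6, 5))
  vol <- intensity_volume(arr, g)
  path <- file.path(tempfile("tif"), "stack.tif")
  dir.create(dirname(path))
  write_stack(vol, path)
  expect_true(file.exists(paste0(path, ".geometry.json")))
  back <- read_stack(path)
  expect_identical(back$values, vol$values)
  expect_equal(back$geometry$voxel_size_um, g$voxel_size_um)
  # 8-bit path
  arr8 <- array(sample.int(256L, 4 * 6 * 5, replace = TRUE) - 1L, c(4, 6, 5))
  write_stack(intensity_volume(arr8, g), path)
  expect_identical(read_stack(path)$values, arr8)
})

test_that("NIfTI stacks round-trip values and micrometre voxel sizes", {
  g <- stack_geometry(c(5, 0.65, 0.65), c(4, 6, 5))
  arr <- array(sample.int(30000L, 4 * 6 * 5, replace = TRUE), c(4, 6, 5))
  path <- tempfile(fileext = ".nii.gz")
  write_stack(intensity_volume(arr, g), path)
  back <- read_stack(path)
  expect_identical(back$values, arr)
  # pixdim is float32 in the NIfTI header, so micrometre voxel sizes
  # round-trip only to single precision
  expect_equal(back$geometry$voxel_size_um, g$voxel_size_um, tolerance = 1e-6)
})

test_that("a 2D-only TIFF without volume metadata is rejected", {
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(20), 4, 5), path, bits.per.sample = 8)
  expect_error(read_stack(path), "2D-only")
})

test_that("non-integer and wrong-unit inputs are rejected with clear errors", {
  expect_error(read_stack(tempfile(fileext = ".png")), "unsupported|not found")
  expect_error(read_stack(tempfile(fileext = ".tif")), "not found")
  # float-valued NIfTI with fractional entries
  path <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(runif(8), c(2, 2, 2)))
  RNifti::writeNifti(img, path, datatype = "float")
  expect_error(read_stack(path), "non-integer")
  # header declaring millimetres must be refused without an override
  path2 <- tempfile(fileext = ".nii.gz")
  img2 <- RNifti::asNifti(array(1L, c(2, 2, 2)))
  img2 <- RNifti::asNifti(img2, reference = list(xyzt_units = 2L))
  RNifti::writeNifti(img2, path2, datatype = "int16")
  expect_error(read_stack(path2), "unit")
  over <- read_stack(path2, geometry_override = c(2, 2, 2))
  expect_equal(over$geometry$voxel_size_um, c(2, 2, 2))
})

test_that("a TIFF without any geometry metadata warns and assumes 1 um", {
  g <- stack_geometry(c(1, 1, 1), c(3, 4, 5))
  arr <- array(1L, c(3, 4, 5))
  path <- tempfile(fileext = ".tif")
  write_stack(intensity_volume(arr, g), path)
  unlink(paste0(path, ".geometry.json"))
  expect_warning(back <- read_stack(path), "assuming 1 um")
  expect_equal(back$geometry$voxel_size_um, c(1, 1, 1))
})

test_that("label maps round-trip with their name sidecar", {
  g <- stack_geometry(c(2, 2, 2), c(3, 4, 5))
  arr <- array(0L, c(3, 4, 5)); arr[1:5] <- 1L; arr[30:40] <- 2L
  lv <- label_volume(arr, g, stats::setNames(c("ed", "vva"), c("1", "2")))
  path <- tempfile(fileext = ".nii.gz")
  write_labels(lv, path)
  expect_true(file.exists(paste0(path, ".labels.txt")))
  back <- read_labels(path, g)
  expect_identical(back$labels, arr)
  expect_identical(unname(back$label_names[c("1", "2")]), c("ed", "vva"))
  # shape mismatch against the expected geometry is an error
  expect_error(read_labels(path, stack_geometry(c(2, 2, 2), c(3, 4, 6))), "shape")
})
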