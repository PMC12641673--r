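test_that("Fleiss kappa reproduces the worked 6x2 example exactly", {
  counts <- rbind(c(3, 0), c(2, 1), c(1, 2), c(0, 3), c(2, 1), c(3, 0))
  res <- fleiss_kappa(rating_matrix(counts, c("macrophage", "background")))
  expect_equal(res$kappa, 23 / 77, tolerance = 1e-15)
  expect_equal(res$pe, 85 / 162, tolerance = 1e-15)
  expect_identical(res$N, 6L)
  expect_identical(res$n, 3L)
})

test_that("perfect agreement across categories gives kappa exactly 1", {
  counts <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(4, 0, 0))
  expect_identical(fleiss_kappa(rating_matrix(counts))$kappa, 1)
})

test_that("single-category ratings raise the degenerate-agreement error", {
  counts <- rbind(c(3, 0), c(3, 0), c(3, 0))
  expect_error(fleiss_kappa(rating_matrix(counts)), "degenerate agreement")
})

test_that("rating matrices are validated", {
  expect_error(rating_matrix(rbind(c(2, 1), c(1, 1))), "same number of raters")
  expect_error(rating_matrix(rbind(c(1, 0), c(0, 1))), "at least 2 raters")
  expect_error(rating_matrix(rbind(c(-1, 4), c(1, 2))), "non-negative")
  expect_error(rating_matrix(matrix(3, 2, 1)), "at least 2 categories")
})

rater_fixture <- function(seed = 5) {
  g <- stack_geometry(c(1, 1, 1), c(6, 6, 6))
  set.seed(seed)
  lapply(1:3, function(i)
    label_volume(array(sample(0:2, 216, replace = TRUE), c(6, 6, 6)), g))
}

test_that("voxel-wise ratings tabulate rater label maps correctly", {
  maps <- rater_fixture()
  rm_ <- build_ratings(maps)
  expect_identical(rm_$n, 3L)
  expect_identical(rm_$N, 216L)
  expect_identical(rm_$categories, 0:2)
  # spot check one voxel: its counts row tabulates the three votes
  lin <- 2L + 6L * (3L - 1L) + 36L * (4L - 1L)  # voxel (2,3,4)
  votes <- vapply(maps, function(m) m$labels[2, 3, 4], integer(1))
  expect_identical(as.vector(rm_$counts[lin, ]), as.vector(table(factor(votes, 0:2))))
  expect_error(build_ratings(maps[1]), "at least 2")
})

test_that("streaming kappa equals the in-memory computation", {
  maps <- rater_fixture(9)
  full <- fleiss_kappa(build_ratings(maps))
  stream <- fleiss_kappa_maps(maps, chunk = 17L)
  expect_equal(stream$kappa, full$kappa, tolerance = 1e-14)
  expect_equal(stream$pe, full$pe, tolerance = 1e-14)
  # restriction masks propagate identically
  msk <- array(rep(c(TRUE, FALSE), length.out = 216), c(6, 6, 6))
  expect_equal(fleiss_kappa_maps(maps, msk, chunk = 10L)$kappa,
               fleiss_kappa(build_ratings(maps, msk))$kappa, tolerance = 1e-14)
})

test_that("per-structure kappa is 1 for identical maps and skips absent structures", {
  g <- stack_geometry(c(1, 1, 1), c(5, 5, 5))
  arr <- array(0L, c(5, 5, 5)); arr[1:10] <- 1L; arr[40:60] <- 2L
  nm <- stats::setNames(c("ed", "vva"), c("1", "2"))
  maps <- list(label_volume(arr, g, nm), label_volume(arr, g, nm))
  res <- per_structure_kappa(maps)
  expect_equal(unname(res$per_structure[c("ed", "vva")]), c(1, 1))
  expect_equal(res$mean, 1)
  expect_warning(res2 <- per_structure_kappa(maps, structures = c("ed", "aqueduct")),
                 "absent")
  expect_identical(res2$skipped, "aqueduct")
})

test_that("simulated raters flip the requested voxel fraction deterministically", {
  g <- stack_geometry(c(1, 1, 1), c(8, 8, 8))
  ref <- array(0L, c(8, 8, 8)); ref[100:220] <- 1L
  ref <- label_volume(ref, g)
  none <- simulate_raters(ref, n_raters = 2, flip_fraction = 0, seed = 1)
  expect_identical(none[[1]]$labels, ref$labels)
  a <- simulate_raters(ref, n_raters = 3, flip_fraction = 0.05, seed = 2)
  b <- simulate_raters(ref, n_raters = 3, flip_fraction = 0.05, seed = 2)
  expect_identical(lapply(a, `[[`, "labels"), lapply(b, `[[`, "labels"))
  flipped <- sum(a[[1]]$labels != ref$labels)
  expect_identical(flipped, as.integer(round(0.05 * 512)))
})
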