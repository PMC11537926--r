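test_that("the hemorrhage cluster is the brightest intracranial one", {
  sl <- test_phantom(size = 128, lesion_px = 400, seed = 5)
  truth_lab <- sl$labels + 1L                 # tissue codes -> cluster ids
  centers <- c(0, 0.23, 0.4, 0.48, 0.71, 1)
  icm <- array(sl$labels %in% 1:4, dim(sl$labels))
  expect_equal(select_hemorrhage_cluster(truth_lab, centers, icm), 5L)
  # without a lesion, the brightest intracranial tissue is chosen
  sl0 <- generate_slice(phantom_spec(size = 64, seed = 5))
  lab0 <- sl0$labels + 1L
  lab0[lab0 == 5] <- 4                        # collapse unused hemorrhage id
  expect_equal(select_hemorrhage_cluster(lab0, centers[1:5],
                                         array(sl0$labels %in% 1:3,
                                               dim(sl0$labels))), 4L)
  # all clusters outside the mask: no lesion
  none <- matrix(FALSE, 128, 128)
  expect_equal(select_hemorrhage_cluster(truth_lab, centers, none), 0L)
  expect_error(select_hemorrhage_cluster(truth_lab, rev(centers)),
               "ascending")
})

test_that("region growing keeps blobs and drops speckle", {
  lab <- matrix(1L, 20, 20)
  lab[5:10, 5:10] <- 2L                      # 36-px blob
  lab[15, 15] <- 2L; lab[15, 16] <- 2L       # 2-px speckle
  rg <- region_grow(lab, 2, min_area_px = 5)
  expect_equal(sum(rg$mask), 36)
  expect_equal(rg$areas, 36)
  # blob alone is preserved exactly
  rg0 <- region_grow(lab, 2, min_area_px = 1)
  expect_equal(sum(rg0$mask), 38)
  expect_true(all(rg0$mask[lab == 2]))
  # subset property: grown mask is inside the seed-cluster pixel set
  expect_true(all(lab[rg$mask] == 2))
  # seed cluster 0 yields an empty mask
  expect_equal(sum(region_grow(lab, 0)$mask), 0)
})

test_that("connectivity semantics split diagonal components", {
  lab <- matrix(1L, 6, 6)
  lab[2, 2] <- 2L; lab[3, 3] <- 2L
  expect_equal(length(region_grow(lab, 2, connectivity = 8,
                                  min_area_px = 1)$areas), 1)
  expect_equal(length(region_grow(lab, 2, connectivity = 4,
                                  min_area_px = 1)$areas), 2)
})

test_that("voxel classification is strict at 0.5", {
  p <- matrix(c(0, 0.5, 0.5001, 1), 2)
  expect_equal(classify_voxels(p), matrix(c(FALSE, FALSE, TRUE, TRUE), 2))
  expect_equal(sum(classify_voxels(matrix(0, 3, 3))), 0)
  expect_error(classify_voxels(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("volume computation converts voxel counts to milliliters", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  expect_equal(compute_volume(m, c(1, 1, 1)), 1)
  m2 <- array(FALSE, c(10, 10, 1)); m2[1:100] <- TRUE
  expect_equal(compute_volume(m2, c(0.5, 0.5, 6)), 0.15)
  expect_equal(compute_volume(array(FALSE, c(4, 4, 2)), c(1, 1, 6)), 0)
  expect_error(compute_volume(m2), "spacing")
  expect_error(compute_volume(m2, c(1, -1, 6)), "positive")
})

test_that("volume is additive over disjoint masks and linear in thickness", {
  set.seed(71)
  a <- array(runif(200) > 0.7, c(10, 10, 2))
  b <- array(runif(200) > 0.7, c(10, 10, 2)) & !a
  sp <- c(0.7, 0.7, 6)
  expect_equal(compute_volume(a | b, sp),
               compute_volume(a, sp) + compute_volume(b, sp))
  expect_equal(compute_volume(a, c(0.7, 0.7, 12)),
               2 * compute_volume(a, sp))
})

test_that("volume strata follow the clinical bins", {
  expect_equal(volume_stratum(c(1, 5, 20, 25, 30)),
               c("<5 mL", "5-25 mL", "5-25 mL", "5-25 mL", ">25 mL"))
})
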