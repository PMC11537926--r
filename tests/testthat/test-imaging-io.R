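test_that("a synthetic DICOM series round-trips voxels and geometry", {
  dir <- withr::local_tempdir()
  set.seed(51)
  slices <- lapply(1:3, function(i) matrix(sample(-200:800, 64, TRUE), 8, 8))
  write_test_series(file.path(dir, "s"), slices, spacing = c(0.5, 0.5, 6))
  vol <- read_dicom_series(file.path(dir, "s"))
  expect_s3_class(vol, "ct_volume")
  expect_equal(dim(vol$voxels), c(8, 8, 3))
  for (i in 1:3) expect_equal(vol$voxels[, , i], slices[[i]])
  expect_equal(vol$spacing, c(0.5, 0.5, 6))
  expect_equal(vol$patient, "PHANTOM")
})

test_that("slice order is recovered from positions regardless of file order", {
  dir <- withr::local_tempdir()
  slices <- lapply(1:3, function(i) matrix(i * 10, 4, 4))
  write_test_series(file.path(dir, "a"), slices, shuffle = FALSE)
  write_test_series(file.path(dir, "b"), slices, shuffle = TRUE)
  va <- read_dicom_series(file.path(dir, "a"))
  vb <- read_dicom_series(file.path(dir, "b"))
  expect_equal(va$voxels, vb$voxels)
})

test_that("DICOM reading rejects bad inputs and warns on missing rescale", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty"); dir.create(empty)
  expect_error(read_dicom_series(empty), "no files")
  mixed <- file.path(dir, "mixed"); dir.create(mixed)
  write_test_dicom(file.path(mixed, "a.dcm"), matrix(1, 4, 4), series = "1.1")
  write_test_dicom(file.path(mixed, "b.dcm"), matrix(1, 4, 4), series = "2.2")
  expect_error(read_dicom_series(mixed), "multiple")
  nores <- file.path(dir, "nores"); dir.create(nores)
  write_test_dicom(file.path(nores, "a.dcm"), matrix(7, 4, 4),
                   omit_rescale = TRUE)
  expect_warning(v <- read_dicom_series(nores), "rescale")
  expect_equal(v$voxels[1, 1, 1], 7)   # identity rescale applied
  notdcm <- file.path(dir, "x"); dir.create(notdcm)
  writeLines("hello", file.path(notdcm, "a.dcm"))
  expect_error(read_dicom_series(notdcm), "DICOM")
})

test_that("NIfTI round-trips voxels and spacing losslessly", {
  set.seed(52)
  arr <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(ct_volume(arr, c(0.5, 0.5, 6)), path)
  back <- read_nifti(path)
  expect_equal(back$voxels, arr)
  expect_equal(back$spacing, c(0.5, 0.5, 6))
  # a 2-D slice is stored as a single-slice volume
  m <- matrix(rnorm(16), 4)
  p2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(m, p2, spacing = c(1, 1, 6))
  b2 <- read_nifti(p2)
  expect_equal(dim(b2$voxels), c(4, 4, 1))
  expect_equal(b2$voxels[, , 1], m)
  expect_error(suppressWarnings(
    read_nifti(withr::local_tempfile(fileext = ".nii"))))
})

test_that("HU windowing maps level and width as specified", {
  expect_equal(apply_window(matrix(40), "brain")[1], 0.5)
  expect_equal(apply_window(matrix(c(-20, -500)), "brain"),
               matrix(c(0, 0)))
  expect_equal(apply_window(matrix(c(100, 900)), "brain"),
               matrix(c(1, 1)))
  expect_equal(apply_window(matrix(640), "skull")[1], 0)
  expect_equal(apply_window(matrix(70), c(40, 120))[1], 0.75)
  expect_error(window_spec(40, 0), "width")
})

test_that("windowing is monotone and commutes with affine HU rescaling", {
  hu <- seq(-100, 200, by = 7)
  w <- apply_window(matrix(hu, 1), "brain")
  expect_true(all(diff(as.vector(w)) >= 0))
  # rescale HU by a positive affine map and match the window
  a <- 2; b <- 30
  w2 <- apply_window(matrix(a * hu + b, 1),
                     window_spec(a * 40 + b, a * 120))
  expect_equal(w, w2)
})

test_that("the dual-window composite stacks brain and skull channels", {
  sl <- matrix(c(-1000, 8, 65, 700), 2)
  comp <- window_composite(sl)
  expect_equal(dim(comp), c(2, 2, 2))
  expect_equal(comp[, , 1], apply_window(sl, "brain"))
  expect_equal(comp[, , 2], apply_window(sl, "skull"))
})

test_that("PNG round trip is exact to the 8-bit quantization step", {
  set.seed(53)
  img <- matrix(runif(512 * 16), 512, 16)
  path <- withr::local_tempfile(fileext = ".png")
  to_png(img, path)
  back <- from_png(path)
  expect_equal(dim(back), dim(img))
  expect_lte(max(abs(back - img)), 1 / 510 + 1e-12)
  to_png(matrix(0, 4, 4), path)
  expect_equal(from_png(path), matrix(0, 4, 4))
  to_png(matrix(1, 4, 4), path)
  expect_equal(from_png(path), matrix(1, 4, 4))
})
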