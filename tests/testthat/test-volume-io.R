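test_that("NRRD write/read round-trips data and geometry exactly", {
  set.seed(41)
  for (i in 1:5) {
    dims <- sample(2:9, 3, replace = TRUE)
    sp <- round(runif(3, 0.1, 1.2), 3)
    or <- round(runif(3, -20, 20), 3)
    v <- random_volume(dims, sp, or)
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_identical(v2$data, v$data)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
    expect_lt(max(abs(v2$origin - v$origin)), 1e-6)
  }
})

test_that("NRRD preserves non-integer intensities and anisotropic spacing", {
  v <- voxel_volume(array(rnorm(60), c(5, 4, 3)), spacing = c(0.3, 0.3, 0.5))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data, tolerance = 1e-15)
  expect_equal(v2$spacing, c(0.3, 0.3, 0.5))
})

test_that("masks round-trip with exact voxel counts, including empty", {
  m <- random_mask(c(12, 11, 10), p = 0.3, spacing = c(0.3, 0.3, 0.3))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(m, f)
  m2 <- read_volume(f, as_mask = TRUE)
  expect_equal(voxel_count(m2), voxel_count(m))
  expect_identical(m2$data, m$data)

  empty <- binary_mask(array(FALSE, c(4, 4, 4)))
  write_volume(empty, f)
  expect_equal(voxel_count(read_volume(f, as_mask = TRUE)), 0)
})

test_that("NIfTI write/read preserves data and geometry", {
  v <- voxel_volume(array(as.double(1:120), c(6, 5, 4)),
                    spacing = c(0.3, 0.4, 0.5), origin = c(1.5, -2, 7))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data)
  expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
  expect_lt(max(abs(v2$origin - v$origin)), 1e-5)
})

test_that("I/O errors are informative", {
  expect_error(read_volume(file.path(tempdir(), "nope.nrrd")), "not found")
  expect_error(read_volume(tempfile(), format = "dicom"), "DICOM")
  f <- withr::local_tempfile(fileext = ".nrrd")
  writeLines("not an nrrd", f)
  expect_error(read_volume(f), "NRRD")
  v <- random_volume()
  expect_error(write_volume(v, file.path(tempdir(), "no_dir_here", "x.nrrd")),
               "directory")
  fx <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", fx)
  expect_error(read_volume(fx), "format")
})

test_that("volume/mask constructors enforce their invariants", {
  expect_error(voxel_volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(voxel_volume(matrix(0, 2, 2)), "3D")
  expect_error(binary_mask(array(NA, c(2, 2, 2))), "NA")
})

test_that("geometry mismatch is detected before any mask combination", {
  a <- random_mask(c(8, 8, 8), spacing = c(1, 1, 1))
  b <- random_mask(c(8, 8, 8), spacing = c(1, 1, 1.001))
  expect_error(measure_change(a, b), "geometry")
  c2 <- random_mask(c(8, 8, 7))
  expect_error(measure_change(a, c2), "geometry")
  # within tolerance passes
  d <- binary_mask(a$data, spacing = c(1, 1, 1 + 1e-9))
  expect_silent(measure_change(a, d))
})

test_that("voxel_to_world maps indices by origin + (index-1)*spacing", {
  v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.3, 0.4, 0.5),
                    origin = c(10, 20, 30))
  expect_equal(as.numeric(voxel_to_world(v, c(1, 1, 1))), c(10, 20, 30))
  expect_equal(as.numeric(voxel_to_world(v, c(2, 3, 4))),
               c(10.3, 20.8, 31.5))
})
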