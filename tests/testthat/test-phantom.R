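test_that("truth lesion counts are exact and reproducible by seed", {
  spec <- tiny_phantom_spec(resorption_voxels = 321, deposition_voxels = 123)
  pair <- make_phantom_pair(spec)
  expect_equal(voxel_count(pair$truth$resorption_mask), 321)
  expect_equal(voxel_count(pair$truth$deposition_mask), 123)
  pair2 <- make_phantom_pair(spec)
  expect_identical(pair2$pre$data, pair$pre$data)   # bit-identical
  expect_identical(pair2$post$data, pair$post$data)
  other <- make_phantom_pair(tiny_phantom_spec(resorption_voxels = 321,
                                               deposition_voxels = 123,
                                               noise_sigma = 20, seed = 9))
  other2 <- make_phantom_pair(tiny_phantom_spec(resorption_voxels = 321,
                                                deposition_voxels = 123,
                                                noise_sigma = 20, seed = 9))
  expect_identical(other$post$data, other2$post$data)
})

test_that("lesion masks are disjoint and confined to the head VOI over many seeds", {
  for (s in 1:50) {
    spec <- tiny_phantom_spec(
      resorption_voxels = sample(50:600, 1),
      deposition_voxels = sample(20:300, 1),
      supersample = 1L, seed = s)
    pair <- make_phantom_pair(spec)
    tr <- pair$truth
    expect_false(any(tr$resorption_mask$data & tr$deposition_mask$data))
    expect_true(voi_contains_mask(tr$head_voi, tr$resorption_mask))
    expect_true(voi_contains_mask(tr$head_voi, tr$deposition_mask))
    expect_equal(voxel_count(crop_voi(tr$resorption_mask, tr$validation_voi)), 0)
    expect_equal(voxel_count(crop_voi(tr$deposition_mask, tr$validation_voi)), 0)
  }
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(bone_intensity = 100, background_intensity = 100),
               "exceed")
  expect_error(phantom_spec(resorption_voxels = -1), ">= 0")
  expect_error(make_phantom_pair(tiny_phantom_spec(resorption_voxels = 1e6)),
               "head")
})

test_that("the pre volume holds a mandible plus a disconnected cranial part", {
  pair <- make_phantom_pair(tiny_phantom_spec())
  bone <- segment_bone(pair$pre, 550)
  lab <- condylovol:::cpp_label_components(as.logical(bone$data), dim(bone$data))
  expect_equal(attr(lab, "n_components"), 2L)
  mand <- select_mandible(bone)
  # the mandibular component excludes every cranial voxel: the cranial slab
  # sits in the top grid slices, the mandible does not reach them
  w <- which(mand$data, arr.ind = TRUE)
  ext <- (dim(bone$data)[3] - 1) * 0.5
  expect_lt(max(w[, 3]), dim(bone$data)[3] - 4)
})

test_that("pulling the posed volume back through the truth transform matches the static pair", {
  spec <- tiny_phantom_spec(pose_offset = c(5, 0, 0, 2, 0, 0), seed = 3)
  pair <- make_phantom_pair(spec)
  static <- make_phantom_pair(tiny_phantom_spec(seed = 3))
  # post-frame -> pre-frame truth transform: resample post onto the pre grid
  aligned <- resample(pair$post, invert_transform(pair$truth$true_transform),
                      reference = pair$pre, interpolation = "nearest",
                      fill = spec$background_intensity)
  # compare where the static post volume is locally constant (2 voxels from
  # any surface): there digitization and nearest lookup are exact
  solid <- static$post$data >= 999.9999
  emptyv <- static$post$data <= 100.0001
  interior <- (!condylovol:::dilate26(condylovol:::dilate26(!solid))) |
    (!condylovol:::dilate26(condylovol:::dilate26(!emptyv)))
  # stay clear of the grid border where the moved FOV has no data
  interior[c(1:6, 43:48), , ] <- FALSE
  interior[, c(1:6, 53:58), ] <- FALSE
  interior[, , c(1:6, 47:52)] <- FALSE
  expect_gt(sum(interior), 20000)
  expect_equal(max(abs(aligned$data[interior] - static$post$data[interior])), 0)
})

test_that("phantom pairs write to disk with a JSON truth sidecar", {
  dir <- withr::local_tempdir()
  pair <- make_phantom_pair(tiny_phantom_spec(resorption_voxels = 100,
                                              deposition_voxels = 40))
  write_phantom_pair(pair, dir)
  expect_true(file.exists(file.path(dir, "pre.nrrd")))
  back <- read_volume(file.path(dir, "post.nrrd"))
  expect_equal(back$data, pair$post$data, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$resorption_voxels, 100)
  expect_equal(truth$head_voi$lower, pair$truth$head_voi$lower)
})
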