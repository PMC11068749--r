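test_that("resample with the identity transform reproduces the input", {
  v <- random_volume(c(10, 9, 8))
  out <- resample(v, rigid_transform())
  expect_equal(out$data, v$data + 0, tolerance = 1e-9)
  m <- random_mask(c(10, 9, 8), spacing = v$spacing)
  expect_identical(resample(m, rigid_transform())$data, m$data)
})

test_that("integer-voxel translation shifts a mask exactly", {
  g <- array(FALSE, c(14, 14, 14))
  g[5:8, 6:9, 5:7] <- TRUE
  m <- binary_mask(g, spacing = c(0.5, 0.5, 0.5))
  # pull convention: sampling input at p + (2,1,-1) voxels moves content the
  # other way; verify against a direct index shift
  tr <- rigid_transform(translation = c(2, 1, -1) * 0.5)
  out <- resample(m, tr)
  expected <- array(FALSE, c(14, 14, 14))
  expected[(5:8) - 2, (6:9) - 1, (5:7) + 1] <- TRUE
  expect_identical(out$data, expected)
  expect_equal(voxel_count(out), voxel_count(m))  # interior mask preserved
})

test_that("content moved fully outside the grid resamples to empty/fill", {
  m <- random_mask(c(8, 8, 8), p = 0.7)
  out <- resample(m, rigid_transform(translation = c(100, 0, 0)))
  expect_equal(voxel_count(out), 0)
  v <- random_volume(c(8, 8, 8))
  out2 <- resample(v, rigid_transform(translation = c(100, 0, 0)), fill = -1)
  expect_true(all(out2$data == -1))
})

test_that("masks refuse interpolating resampling", {
  m <- random_mask(c(6, 6, 6))
  expect_error(resample(m, rigid_transform(), interpolation = "linear"),
               "nearest")
  expect_error(resample(m, rigid_transform(), interpolation = "cubic"),
               "nearest")
})

test_that("mask round-trip through a rotation and back keeps >= 99% of voxels", {
  pair <- make_phantom_pair(tiny_phantom_spec(resorption_voxels = 300,
                                              deposition_voxels = 0))
  lesion <- pair$truth$resorption_mask
  tr <- rigid_transform(c(4, -3, 6), c(1.2, -0.7, 0.4),
                        center = c(12, 14.4, 14))
  fwd <- resample(lesion, tr)
  back <- resample(fwd, invert_transform(tr))
  expect_gte(sum(back$data & lesion$data), 0.99 * voxel_count(lesion))
})

test_that("self-registration recovers the identity", {
  pair <- make_phantom_pair(tiny_phantom_spec(blur_sigma = 0.3))
  mand <- select_mandible(segment_bone(pair$pre,
                                       max_entropy_threshold(pair$pre)))
  vol <- crop_by_mask(pair$pre, dilate_mask(mand, 4))
  tr <- register_rigid(vol, vol, register_params(shrink = c(2L, 1L),
                                                 smooth = c(1, 0)),
                       fixed_mask = dilate_mask(mand, 2))
  m <- transform_magnitude(tr, at = c(12, 14.4, 17))
  expect_lt(m[["angle_deg"]], 0.1)
  expect_lt(m[["displacement_mm"]], 0.05 * 0.5)  # 0.05 voxel
})

test_that("registration recovers a known pose on the half-scale phantom", {
  pair <- make_phantom_pair(tiny_phantom_spec(
    pose_offset = c(4, 0, 0, 1.5, 0, 0), blur_sigma = 0.3))
  thr <- max_entropy_threshold(pair$pre)
  mand <- select_mandible(segment_bone(pair$pre, thr))
  mand2 <- select_mandible(segment_bone(pair$post, thr))
  fixedv <- crop_by_mask(pair$pre, dilate_mask(mand, 4))
  movingv <- crop_by_mask(pair$post, dilate_mask(mand2, 4))
  tr <- register_rigid(fixedv, movingv, fixed_mask = dilate_mask(mand, 2))
  err <- compose_transforms(tr, pair$truth$true_transform)
  m <- transform_magnitude(err, at = c(12, 14.4, 17))
  expect_lt(m[["angle_deg"]], 0.25)
  expect_lt(m[["displacement_mm"]] / 0.5, 0.25)   # voxels at 0.5 mm
})

test_that("degenerate registration inputs raise errors", {
  flat <- voxel_volume(array(1, c(6, 6, 6)))
  v <- random_volume(c(6, 6, 6))
  expect_error(register_rigid(flat, v), "constant")
  expect_error(register_rigid(v, flat), "constant")
})
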