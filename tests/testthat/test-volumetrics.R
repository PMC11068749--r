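test_that("crop_voi crops shape and advances the origin", {
  v <- random_volume(c(12, 12, 12), spacing = c(0.3, 0.3, 0.3),
                     origin = c(1, 2, 3))
  full <- voi_box(c(1, 1, 1), c(13, 13, 13))
  expect_identical(crop_voi(v, full)$data, v$data)
  voi <- voi_box(c(2, 3, 4), c(12, 13, 14) - 0)
  expect_error(crop_voi(v, voi), "bounds")
  voi <- voi_box(c(2, 3, 4), c(12, 13, 13))
  out <- crop_voi(v, voi)
  expect_equal(dim(out$data), c(10, 10, 9))
  expect_equal(out$origin, c(1, 2, 3) + c(1, 2, 3) * 0.3)
  expect_identical(out$data, v$data[2:11, 3:12, 4:12])
  # count of true voxels inside the box, by index scan
  m <- random_mask(c(12, 12, 12), p = 0.4, spacing = v$spacing)
  w <- which(m$data, arr.ind = TRUE)
  inside <- sum(w[, 1] >= 2 & w[, 1] < 12 & w[, 2] >= 3 & w[, 2] < 13 &
                  w[, 3] >= 4 & w[, 3] < 13)
  expect_equal(voxel_count(crop_voi(m, voi)), inside)
})

test_that("voi_box validates its bounds", {
  expect_error(voi_box(c(1, 1, 1), c(1, 2, 2)), "lower < upper")
  expect_error(voi_box(c(0, 1, 1), c(2, 2, 2)), ">= 1")
})

test_that("auto_head_voi proposes adjacent boxes with shared transverse extents", {
  pair <- make_phantom_pair(tiny_phantom_spec())
  thr <- max_entropy_threshold(pair$pre)
  mand <- select_mandible(segment_bone(pair$pre, thr))
  vois <- auto_head_voi(mand, mand, neck_height = 15L)
  expect_equal(vois$validation$upper[3], vois$head$lower[3])  # zero gap
  expect_equal(vois$validation$lower[1:2], vois$head$lower[1:2])
  expect_equal(vois$validation$upper[1:2], vois$head$upper[1:2])
  expect_equal(vois$head$lower[3] - vois$validation$lower[3], 15L)
  # head box contains both truth lesion masks entirely
  expect_true(voi_contains_mask(vois$head, pair$truth$resorption_mask))
  expect_true(voi_contains_mask(vois$head, pair$truth$deposition_mask))
  # validation region is lesion-free
  expect_equal(voxel_count(crop_voi(pair$truth$resorption_mask,
                                    vois$validation)), 0)
  expect_error(auto_head_voi(mand, mand, neck_height = 500L), "too short")
})

test_that("measure_change handles identical, nested and random mask pairs", {
  m <- random_mask(c(15, 15, 15), p = 0.5, spacing = c(0.3, 0.3, 0.3))
  same <- measure_change(m, m)
  expect_equal(same$dV, 0)
  expect_equal(same$dV_minus, 0)
  expect_equal(same$dV_plus, 0)
  expect_equal(same$overlap, same$Vpre)

  sup <- m$data
  drop_idx <- sample(which(sup), 37)
  sub <- sup; sub[drop_idx] <- FALSE
  rec <- measure_change(binary_mask(sup, m$spacing), binary_mask(sub, m$spacing))
  expect_equal(rec$dV_minus, 37)
  expect_equal(rec$dV_plus, 0)
  expect_equal(rec$dV, -37)

  set.seed(21)
  for (i in 1:10) {
    a <- random_mask(c(20, 20, 20), p = runif(1, 0.1, 0.9))
    b <- random_mask(c(20, 20, 20), p = runif(1, 0.1, 0.9))
    got <- measure_change(a, b)
    want <- oracle_overlap_tally(a, b)
    for (f in names(want)) expect_equal(got[[f]], want[[f]])
  }
})

test_that("measure_change is antisymmetric and mm3 fields are consistent", {
  a <- random_mask(c(12, 12, 12), p = 0.5, spacing = c(0.3, 0.3, 0.3))
  b <- random_mask(c(12, 12, 12), p = 0.5, spacing = c(0.3, 0.3, 0.3))
  ab <- measure_change(a, b)
  ba <- measure_change(b, a)
  expect_equal(ab$dV_plus, ba$dV_minus)
  expect_equal(ab$dV_minus, ba$dV_plus)
  expect_equal(ab$dV, -ba$dV)
  expect_equal(ab$dV_mm3, ab$dV * 0.027)
  expect_equal(ab$Vpre_mm3, ab$Vpre * 0.027)
})

test_that("change_masks partitions the symmetric difference", {
  a <- random_mask(c(10, 10, 10), p = 0.5)
  b <- random_mask(c(10, 10, 10), p = 0.5)
  cm <- change_masks(a, b)
  rec <- measure_change(a, b)
  expect_equal(voxel_count(cm$resorption), rec$dV_minus)
  expect_equal(voxel_count(cm$deposition), rec$dV_plus)
  expect_false(any(cm$resorption$data & cm$deposition$data))
})

test_that("mesh volume agrees with analytic volumes of digitized solids", {
  cube <- cube_mask(20)
  expect_equal(mesh_volume(cube) / (20^3 * 0.027), 1, tolerance = 0.05)
  sph <- ball_mask(15)
  expect_equal(mesh_volume(sph) / (4 / 3 * pi * (15 * 0.3)^3), 1,
               tolerance = 0.03)
  # voxel-count volume and surface volume agree for convex bodies
  expect_equal(mesh_volume(sph) / (voxel_count(sph) * 0.027), 1,
               tolerance = 0.05)
  expect_error(mesh_volume(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
  # a mask touching the grid border still yields a closed surface
  edge <- binary_mask(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(mesh_volume(edge), 64, tolerance = 0.1 * 64)
})
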