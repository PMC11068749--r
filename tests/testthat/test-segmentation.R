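test_that("max-entropy threshold equals the exhaustive criterion scan", {
  set.seed(11)
  for (i in 1:8) {
    n <- 400
    vals <- c(rnorm(n * 0.7, 100, 30), rnorm(n * 0.3, 1000, 30),
              runif(n * 0.1, 0, 1200))
    v <- voxel_volume(array(vals[1:396], c(6, 6, 11)))
    n_bins <- sample(c(64L, 128L, 256L), 1)
    got <- max_entropy_threshold(v, n_bins)
    expect_equal(got$threshold,
                 oracle_max_entropy(as.numeric(v$data), n_bins),
                 tolerance = 1e-12)
    # invariants: inside the occupied range, criterion max at the threshold
    expect_gt(got$threshold, min(vals))
    expect_lt(got$threshold, max(vals))
    s <- which(got$histogram$breaks == got$threshold) - 1
    expect_equal(got$criterion_curve[s],
                 max(got$criterion_curve, na.rm = TRUE))
  }
})

test_that("bimodal volumes threshold strictly between the modes", {
  set.seed(12)
  vals <- c(rnorm(3000, 100, 30), rnorm(3000, 1000, 30))
  v <- voxel_volume(array(vals, c(20, 20, 15)))
  thr <- max_entropy_threshold(v)$threshold
  expect_gt(thr, 100)
  expect_lt(thr, 1000)
})

test_that("threshold bin index is invariant under intensity scaling", {
  set.seed(13)
  vals <- c(rnorm(500, 100, 40), rnorm(300, 900, 50))
  v1 <- voxel_volume(array(vals, c(10, 10, 8)))
  v2 <- voxel_volume(array(vals * 3.5, c(10, 10, 8)))
  t1 <- max_entropy_threshold(v1, 128)
  t2 <- max_entropy_threshold(v2, 128)
  expect_equal(which(t1$histogram$breaks == t1$threshold),
               which(t2$histogram$breaks == t2$threshold))
  expect_equal(t2$threshold, t1$threshold * 3.5, tolerance = 1e-9)
})

test_that("degenerate and invalid thresholding inputs raise errors", {
  flat <- voxel_volume(array(7, c(4, 4, 4)))
  expect_error(max_entropy_threshold(flat), "degenerate|constant")
  v <- random_volume()
  expect_error(max_entropy_threshold(v, n_bins = 1), "n_bins")
})

test_that("segment_bone applies >= threshold and is monotone", {
  v <- random_volume(c(8, 8, 8), max_val = 100)
  expect_equal(voxel_count(segment_bone(v, 1000)), 0)         # all below
  expect_equal(voxel_count(segment_bone(v, min(v$data))), 512) # full mask
  m50 <- segment_bone(v, 50)
  m80 <- segment_bone(v, 80)
  expect_true(all(m50$data[m80$data]))  # raising threshold never adds voxels
  expect_identical(m50$data, v$data >= 50)
})

test_that("select_mandible keeps one 26-connected component", {
  g <- array(FALSE, c(12, 12, 12))
  g[2:5, 2:5, 2:5] <- TRUE          # 64-voxel component
  g[8:11, 8:11, 8:9] <- TRUE        # 32-voxel component
  m <- binary_mask(g)
  big <- select_mandible(m)
  expect_equal(voxel_count(big), 64)
  small <- select_mandible(m, seed_point = c(9, 9, 8))
  expect_equal(voxel_count(small), 32)
  # output is a subset of input and one component
  expect_true(all(m$data[big$data]))
  lab <- condylovol:::cpp_label_components(as.logical(big$data), dim(big$data))
  expect_equal(attr(lab, "n_components"), 1L)
  # diagonal touching is connected under 26-connectivity
  gd <- array(FALSE, c(4, 4, 4)); gd[1, 1, 1] <- TRUE; gd[2, 2, 2] <- TRUE
  expect_equal(voxel_count(select_mandible(binary_mask(gd))), 2)
  expect_error(select_mandible(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
  expect_error(select_mandible(m, seed_point = c(1, 1, 12)), "component")
})

test_that("crop_by_mask keeps masked intensities and fills the rest", {
  v <- random_volume(c(9, 9, 9))
  full <- binary_mask(array(TRUE, c(9, 9, 9)), v$spacing)
  expect_identical(crop_by_mask(v, full)$data, v$data)
  none <- binary_mask(array(FALSE, c(9, 9, 9)), v$spacing)
  expect_true(all(crop_by_mask(v, none, fill = -5)$data == -5))
  m <- random_mask(c(9, 9, 9), p = 0.4, spacing = v$spacing)
  cropped <- crop_by_mask(v, m)
  expect_equal(sum(cropped$data), sum(v$data[m$data]))  # summation oracle
  vbad <- random_volume(c(8, 9, 9))
  expect_error(crop_by_mask(vbad, m), "geometry")
})

test_that("median filter matches a brute-force neighborhood-median loop", {
  set.seed(14)
  v <- random_volume(c(12, 12, 12), max_val = 500)
  got <- median_filter_3d(v, 1)
  d <- dim(v$data)
  for (idx in list(c(1, 1, 1), c(6, 7, 5), c(12, 12, 12), c(1, 12, 6))) {
    i <- idx[1]; j <- idx[2]; k <- idx[3]
    nb <- v$data[max(1, i - 1):min(d[1], i + 1),
                 max(1, j - 1):min(d[2], j + 1),
                 max(1, k - 1):min(d[3], k + 1)]
    expect_equal(got$data[i, j, k], median(nb))
  }
  # full-volume check against an all-voxel oracle on a smaller grid
  w <- random_volume(c(6, 6, 6), max_val = 50)
  gotw <- median_filter_3d(w, 1)
  ow <- array(0, c(6, 6, 6))
  for (k in 1:6) for (j in 1:6) for (i in 1:6)
    ow[i, j, k] <- median(w$data[max(1, i - 1):min(6, i + 1),
                                 max(1, j - 1):min(6, j + 1),
                                 max(1, k - 1):min(6, k + 1)])
  expect_equal(gotw$data, ow)
})

test_that("median filter removes impulses, fixes constants, radius 0 is identity", {
  z <- array(0, c(9, 9, 9)); z[5, 5, 5] <- 100
  v <- voxel_volume(z)
  expect_true(all(median_filter_3d(v, 2)$data == 0))
  flat <- voxel_volume(array(3, c(5, 5, 5)))
  expect_identical(median_filter_3d(flat, 2)$data, flat$data)
  r <- random_volume()
  expect_identical(median_filter_3d(r, 0)$data, r$data)
  expect_error(median_filter_3d(r, -1), "radius")
  # output values come from the input value set (or midpoints of two input
  # values where the edge-truncated neighborhood has even size)
  m <- median_filter_3d(random_volume(c(7, 7, 7), max_val = 9), 1)
  expect_true(all(m$data %in% seq(1, 9, by = 0.5)))
})

test_that("dilate_mask grows by the 26-neighborhood", {
  g <- array(FALSE, c(7, 7, 7)); g[4, 4, 4] <- TRUE
  d1 <- dilate_mask(binary_mask(g), 1)
  expect_equal(voxel_count(d1), 27)
  expect_equal(voxel_count(dilate_mask(binary_mask(g), 2)), 125)
  expect_identical(dilate_mask(binary_mask(g), 0)$data, g)
})
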