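# Bidimensional measurement engine: slice selection, diameter geometry vs a
# brute-force oracle, growth classification and consensus.

test_that("largest cross-section converts area and breaks ties to the lower slice", {
  acq <- fine_acq(n_slices = 5L, n = 32L)
  mask <- array(FALSE, acq$grid_shape)
  mask[2, 11:20, 11:20] <- TRUE       # 100 voxels at 1 mm^2
  lv <- label_volume(mask, acq)
  sel <- largest_cross_section(lv)
  expect_identical(sel$slice_index, 2L)
  expect_equal(sel$area_cm2, 1.00)

  mask[4, 11:20, 11:20] <- TRUE       # equal-area tie
  sel2 <- largest_cross_section(label_volume(mask, acq))
  expect_identical(sel2$slice_index, 2L)

  empty <- label_volume(array(FALSE, acq$grid_shape), acq, check = FALSE)
  expect_error(largest_cross_section(empty), "no tumor")
})

test_that("a digital sphere is measured at its equatorial slice", {
  acq <- fine_acq(n_slices = 32L, n = 48L)
  spec <- trajectory_spec(c(15, 15, 12), "stable", scan_times = c(0, .5, 1, 1.5))
  subj <- generate_cohort(list(spec), acq, seed = 2)[[1]]
  sel <- largest_cross_section(subj$scans[[1]]$label)
  counts <- apply(subj$scans[[1]]$label$mask, 1, sum)
  expect_identical(sel$slice_index, which.max(counts))
  # equator of a z-symmetric body sits at the central slices
  expect_lte(abs(sel$slice_index - 16.5), 1.6)
})

test_that("digital disk: d1 and d2 agree with the 4 cm diameter and 16 cm^2 product", {
  bd <- bidiameter(disk_slice(64L, radius = 20), 1)
  expect_equal(bd$d1_cm, 4.0, tolerance = 0.1 / 4)   # within 1 voxel caliper
  expect_equal(bd$d2_cm, 4.0, tolerance = 0.1 / 4)
  expect_equal(bd$d1_cm * bd$d2_cm, 16, tolerance = 0.05)
  expect_false(bd$degenerate)
})

test_that("axis-aligned rectangle: d1 is the diagonal, d2 the longest near-perpendicular chord", {
  m <- matrix(FALSE, 50, 20)
  m[3:42, 3:12] <- TRUE               # 40 x 10 voxel rectangle
  bd <- bidiameter(m, 1)
  oracle <- oracle_bidiameter(m, 1)
  expect_equal(bd$d1_cm, sqrt(39^2 + 9^2) / 10)
  expect_equal(bd$d1_cm, oracle$d1_cm, tolerance = 0)
  expect_equal(bd$d2_cm, oracle$d2_cm, tolerance = 0)
})

test_that("engine equals the exhaustive boundary-pair oracle on random blobs", {
  set.seed(77)
  for (case in seq_len(50)) {
    m <- random_blob()
    if (!any(m)) next
    bd <- bidiameter(m, 1)
    oracle <- oracle_bidiameter(m, 1)
    expect_equal(bd$d1_cm, oracle$d1_cm, tolerance = 0)
    expect_equal(bd$d2_cm, oracle$d2_cm, tolerance = 0)
  }
})

test_that("rotating a mask by 90 degrees changes the diameters by at most one caliper", {
  set.seed(5)
  for (case in seq_len(10)) {
    m <- random_blob()
    r <- t(m[nrow(m):1, ])            # 90-degree rotation
    a <- bidiameter(m, 1)
    b <- bidiameter(r, 1)
    expect_lte(abs(a$d1_cm - b$d1_cm), 0.1)
    expect_lte(abs(a$d2_cm - b$d2_cm), 0.1)
  }
})

test_that("dilation never decreases d1 or the cross-section area", {
  set.seed(9)
  for (case in seq_len(10)) {
    m <- random_blob(n = 44L)
    md <- ranovol:::dilate_mask(m, 1L)
    if (any(md[1, ]) || any(md[nrow(md), ]) || any(md[, 1]) || any(md[, ncol(md)]))
      next
    expect_gte(bidiameter(md, 1)$d1_cm, bidiameter(m, 1)$d1_cm)
    expect_gte(sum(ranovol:::largest_component(md)),
               sum(ranovol:::largest_component(m)))
  }
})

test_that("a disjoint satellite smaller than the main component never changes the measurement", {
  m <- disk_slice(64L, radius = 14, center = c(25, 25))
  with_sat <- m | disk_slice(64L, radius = 4, center = c(54, 54))
  a <- bidiameter(m, 1)
  b <- bidiameter(with_sat, 1)
  expect_identical(a[c("d1_cm", "d2_cm")], b[c("d1_cm", "d2_cm")])

  acq <- fine_acq(n_slices = 5L, n = 64L)
  expect_identical(rano_measure(single_slice_volume(m, acq))$product,
                   rano_measure(single_slice_volume(with_sat, acq))$product)
})

test_that("single-voxel components fall back to the voxel caliper width, flagged", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  bd <- bidiameter(m, 1)
  expect_true(bd$degenerate)
  expect_equal(bd$d1_cm, 0.1)
  expect_equal(bd$d2_cm, 0.1)
})

test_that("growth classification applies the 25% rule inclusively by default", {
  g <- classify_growth(9.43, 9.08)
  expect_equal(round(g$percent_change), 4)
  expect_identical(g$call, 0L)

  edge <- classify_growth(5.00, 4.00)
  expect_equal(edge$percent_change, 25)
  expect_identical(edge$call, 1L)
  expect_identical(classify_growth(5.00, 4.00, inclusive = FALSE)$call, 0L)

  same <- classify_growth(7.5, 7.5)
  expect_equal(same$percent_change, 0)
  expect_identical(same$call, 0L)

  expect_error(classify_growth(1, 0), "positive")
})

test_that("consensus follows the two-of-three rule", {
  expect_identical(consensus_call(c(1, 1, 0)), 1L)
  expect_identical(consensus_call(c(1, 0, 0)), 0L)
  expect_identical(consensus_call(c(0, 0, 0)), 0L)
  expect_identical(consensus_call(c(1, 1, 1, 0, 0), k = 3), 1L)
  expect_error(consensus_call(integer(0)), "empty")
})

test_that("measurement product is exactly d1 times d2", {
  set.seed(21)
  for (case in seq_len(5)) {
    m <- random_blob()
    acq <- fine_acq(n_slices = 5L, n = nrow(m))
    meas <- rano_measure(single_slice_volume(m, acq))
    expect_identical(meas$product, meas$d1 * meas$d2)
  }
})
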