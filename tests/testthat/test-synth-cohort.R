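# Synthetic cohort generator: determinism, volume ground truth, growth
# models, satellite disjointness, operator read model, intensity rendering.

test_that("stable trajectories keep the discretized volume nearly constant", {
  acq <- fine_acq(n_slices = 26L, n = 48L)
  spec <- trajectory_spec(c(15, 12, 10), "stable",
                          scan_times = seq(0, 2, 0.5))
  subj <- generate_cohort(list(spec), acq, seed = 11)[[1]]
  vols <- vapply(subj$scans, function(s) compute_volume(s$label), numeric(1))
  expect_lt(diff(range(vols)) / mean(vols), 0.02)
})

test_that("discretized ellipsoid volume matches the analytic value within 5%", {
  acq <- fine_acq(n_slices = 26L, n = 48L)
  spec <- trajectory_spec(c(20, 15, 10), "stable",
                          scan_times = c(0, 0.5, 1, 1.5))
  subj <- generate_cohort(list(spec), acq, seed = 3)[[1]]
  analytic <- 4 / 3 * pi * 20 * 15 * 10 / 1000
  expect_lt(abs(compute_volume(subj$scans[[1]]$label) - analytic) / analytic,
            0.05)
  expect_equal(subj$true_volumes_cm3[1], analytic)
})

test_that("change-point growth multiplies the true volume per scan after onset", {
  acq <- fine_acq(n_slices = 34L, n = 72L)
  spec <- trajectory_spec(c(14, 12, 10), "change_point", change_time = 3L,
                          growth_rate = 0.3, scan_times = seq(0, 2.5, 0.5))
  subj <- generate_cohort(list(spec), acq, seed = 5)[[1]]
  tv <- subj$true_volumes_cm3
  expect_equal(tv[2] / tv[1], 1)
  expect_equal(tv[4] / tv[3], 1.3)
  expect_equal(tv[6] / tv[5], 1.3)
  # discretized masks realize the same ratio up to voxelization
  dv <- vapply(subj$scans, function(s) compute_volume(s$label), numeric(1))
  expect_equal(dv[4] / dv[3], 1.3, tolerance = 0.05)
  expect_identical(subj$true_change_index, 3L)
  expect_equal(subj$true_onset_time, 1.5)
})

test_that("cohort generation is deterministic given the seed", {
  acq <- fine_acq(n_slices = 26L, n = 40L)
  spec <- trajectory_spec(c(10, 9, 8), "stable", margin_irregularity = 0.15,
                          scan_times = c(0, 0.5, 1, 1.5))
  a <- generate_cohort(list(spec), acq, seed = 42)[[1]]
  b <- generate_cohort(list(spec), acq, seed = 42)[[1]]
  expect_identical(a$scans[[1]]$label$mask, b$scans[[1]]$label$mask)
  c2 <- generate_cohort(list(spec), acq, seed = 43)[[1]]
  expect_false(identical(a$scans[[1]]$label$mask, c2$scans[[1]]$label$mask))
})

test_that("satellites are disjoint components and never merge with the main lesion", {
  acq <- acquisition_params(1, 2, 2, c(36L, 96L, 96L))
  spec <- trajectory_spec(c(12, 10, 8), "change_point", change_time = 2L,
                          growth_rate = 0.35, satellite_count = 2L,
                          growth_site = "satellite", main_growth_rate = 0.1,
                          scan_times = seq(0, 2.5, 0.5))
  subj <- generate_cohort(list(spec), acq, seed = 7)[[1]]
  for (s in subj$scans) {
    expect_identical(max(ranovol:::label_components(s$label$mask)), 3L)
  }
})

test_that("oversized tumors and degenerate radii are rejected with the subject named", {
  acq <- fine_acq(n_slices = 5L, n = 20L)
  spec <- trajectory_spec(c(15, 15, 10), "stable", scan_times = c(0, 0.5, 1, 1.5))
  expect_error(generate_cohort(list(spec), acq, seed = 1), "S001")
  spec2 <- trajectory_spec(c(10, 9, 0.5), "stable", scan_times = c(0, 0.5, 1, 1.5))
  expect_error(generate_cohort(list(spec2), fine_acq(), seed = 1), "degenerate")
})

test_that("trajectory_spec enforces its invariants", {
  expect_error(trajectory_spec(c(10, 9, 8), "stable", scan_times = c(0, 0.5, 1)),
               ">= 4")
  expect_error(trajectory_spec(c(10, 9, 8), "change_point",
                               scan_times = c(0, 0.5, 1, 1.5)),
               "change_time")
  expect_error(trajectory_spec(c(10, 9, 8), "stable", change_time = 2,
                               scan_times = c(0, 0.5, 1, 1.5)),
               "change_time")
})

test_that("noise-free operator reads return the true measurement", {
  truth <- rano_measurement(3L, 3.0, 2.0)
  model <- operator_model(3L, 0, 0, seed = 1)
  reads <- simulate_operator_reads(truth, model)
  expect_equal(reads$d1_cm, rep(3.0, 3))
  expect_equal(reads$d2_cm, rep(2.0, 3))
  expect_equal(reads$product_cm2, rep(6.0, 3))
})

test_that("between-operator spread of products exceeds within-operator spread", {
  truth <- rano_measurement(3L, 3.0, 2.0)
  model <- operator_model(3L, inter_sd_frac = 0.15, intra_sd_frac = 0.05,
                          seed = 1)
  # 200 subjects, one read per operator each, biases redrawn per subject
  prods <- t(vapply(seq_len(200), function(i) {
    simulate_operator_reads(truth, model, seed = 1000 + i)$product_cm2
  }, numeric(3)))
  # within-operator SD across subjects mixes bias and read noise per column;
  # compare the between-operator variance of subject means against the
  # within-subject residual variance instead
  between <- mean(apply(prods, 1, stats::var))
  model0 <- operator_model(3L, inter_sd_frac = 0, intra_sd_frac = 0.05,
                           seed = 1)
  prods0 <- t(vapply(seq_len(200), function(i) {
    simulate_operator_reads(truth, model0, seed = 1000 + i)$product_cm2
  }, numeric(3)))
  within <- mean(apply(prods0, 1, stats::var))
  expect_gt(between, within)
})

test_that("symmetric intra-operator noise gives near-zero Bland-Altman mean difference", {
  truth <- rano_measurement(3L, 3.0, 2.0)
  model <- operator_model(2L, inter_sd_frac = 0, intra_sd_frac = 0.3, seed = 9)
  prods <- t(vapply(seq_len(400), function(i) {
    simulate_operator_reads(truth, model, seed = 2000 + i)$product_cm2
  }, numeric(2)))
  ba <- bland_altman(prods[, 1], prods[, 2])
  # Monte-Carlo bound: 3 SE of the mean percent difference
  expect_lt(abs(ba$mean_percent_diff), 3 * ba$sd_percent / sqrt(ba$n_pairs))
})

test_that("operator read model rejects negative noise SDs", {
  expect_error(operator_model(3L, -0.1, 0.05), ">= 0")
})

test_that("intensity rendering is exact without noise and unbiased with it", {
  subj0 <- phantom_subject(noise_sd = 0)
  img0 <- subj0$scans[[1]]$intensity
  expect_setequal(unique(as.vector(img0$values)), c(5, 40, 60, 100))
  expect_true(all(img0$values[subj0$scans[[1]]$label$mask] == 100))

  subj <- phantom_subject(noise_sd = 5)
  img <- subj$scans[[1]]$intensity
  tum <- img$values[subj$scans[[1]]$label$mask]
  expect_gt(length(tum), 1000)
  expect_equal(mean(tum), 100, tolerance = 0.01)

  # empty mask: non-tumor classes only
  acq <- fine_acq(n_slices = 12L, n = 32L)
  lv <- label_volume(array(FALSE, acq$grid_shape), acq, check = FALSE)
  img_e <- render_intensity(lv, noise_sd = 0)
  expect_setequal(unique(as.vector(img_e$values)), c(5, 40, 60))
})

test_that("rendering is deterministic given the seed and validates class order", {
  subj <- phantom_subject()
  lv <- subj$scans[[1]]$label
  a <- render_intensity(lv, noise_sd = 5, seed = 4)
  b <- render_intensity(lv, noise_sd = 5, seed = 4)
  expect_identical(a$values, b$values)
  expect_error(render_intensity(lv, class_means = c(background = 5,
                                                    gray_matter = 90,
                                                    white_matter = 40,
                                                    tumor = 80)),
               "exceed")
})
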