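# Agreement statistics: regression agreement, CV, Bland-Altman, kappa, and
# the printed interpretation bands.

test_that("identity and pure-scale inputs give the expected r2 and CV", {
  x <- c(2.1, 3.4, 5.0, 7.7, 9.2)
  a <- regression_agreement(x, x)
  expect_equal(a$r2, 1)
  expect_equal(a$cv_percent, 0)
  expect_equal(a$mean_percent_diff, 0)
  expect_equal(a$loa_low, 0)
  expect_equal(a$loa_high, 0)
  expect_identical(a$interpretation, "excellent")

  b <- regression_agreement(x, 2 * x)   # correlation is scale-blind
  expect_equal(b$r2, 1)
  expect_gt(b$cv_percent, 0)
})

test_that("zero-variance input reports r2 as undefined, not zero", {
  a <- regression_agreement(rep(3, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(a$r2))
  expect_match(a$note, "undefined")
})

test_that("simulated operator reads recover the dialed-in variability", {
  truth <- rano_measurement(3L, 3.0, 2.0)
  model <- operator_model(2L, inter_sd_frac = 0.2, intra_sd_frac = 0, seed = 1)
  prods <- t(vapply(seq_len(500), function(i) {
    simulate_operator_reads(truth, model, seed = 3000 + i)$product_cm2
  }, numeric(2)))
  a <- regression_agreement(prods[, 1], prods[, 2])
  # Monte-Carlo truth for the same CV functional, computed directly
  # with zero intra-operator noise each operator scales both diameters by
  # the same (1 + bias), so the product scales by (1 + bias)^2
  mc <- replicate(2000, {
    s <- pmax(1 + rnorm(2, 0, 0.2), 0.1)
    truth$product * s^2
  })
  cv_true <- 100 * sd(mc[1, ] - mc[2, ]) / mean(mc)
  expect_equal(a$cv_percent, cv_true, tolerance = 0.2)
})

test_that("Bland-Altman closed form: y = 1.25 x gives a constant -22.2% difference", {
  x <- c(2, 4, 6, 8)
  ba <- bland_altman(x, 1.25 * x)
  expect_equal(ba$mean_percent_diff, 100 * (1 - 1.25) / 1.125)
  expect_equal(ba$sd_percent, 0)
  expect_equal(ba$loa_low, ba$mean_percent_diff)
  expect_equal(ba$loa_high, ba$mean_percent_diff)
})

test_that("Bland-Altman mean difference is antisymmetric under rater swap", {
  set.seed(8)
  x <- runif(30, 2, 10); y <- x * exp(rnorm(30, 0, 0.2))
  expect_equal(bland_altman(x, y)$mean_percent_diff,
               -bland_altman(y, x)$mean_percent_diff)
  # r2 and kappa are symmetric under swap
  expect_equal(regression_agreement(x, y)$r2, regression_agreement(y, x)$r2)
  a <- rbinom(40, 1, 0.5); b <- ifelse(runif(40) < 0.8, a, 1 - a)
  expect_equal(cohens_kappa(a, b)$kappa, cohens_kappa(b, a)$kappa)
})

test_that("kappa matches the hand-computed 2x2 table and identity convention", {
  a <- c(rep(1, 25), rep(0, 25))
  b <- c(rep(1, 20), rep(0, 5), rep(1, 10), rep(0, 15))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.7)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.4)

  ident <- cohens_kappa(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(ident$kappa, 1)
  # both raters constant and agreeing: kappa = 1 by convention
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5))$kappa, 1)
  expect_error(cohens_kappa(c(0, 1), c(0, 1, 1)), "length")
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (i in seq_len(10)) {
    a <- rbinom(60, 1, 0.4)
    b <- ifelse(runif(60) < 0.7, a, rbinom(60, 1, 0.5))
    lev <- c(0, 1)
    tab <- table(factor(a, lev), factor(b, lev))
    expect_equal(cohens_kappa(a, b)$kappa,
                 e1071::classAgreement(tab)$kappa)
  }
})

test_that("kappa on independent raters is near zero (null Monte Carlo)", {
  set.seed(44)
  n <- 10000
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.5)
  k <- cohens_kappa(a, b)
  expect_lt(abs(k$kappa), 3 * k$se)
  expect_identical(k$interpretation,
                   agreement_band(k$kappa, "kappa"))
})

test_that("interpretation bands follow the printed ranges with inclusive upper edges", {
  expect_identical(agreement_band(0, "correlation"), "poor")
  expect_identical(agreement_band(0.20, "correlation"), "slight")
  expect_identical(agreement_band(0.21, "correlation"), "fair")
  expect_identical(agreement_band(0.60, "correlation"), "moderate")
  expect_identical(agreement_band(0.80, "correlation"), "good")
  expect_identical(agreement_band(1.00, "correlation"), "excellent")
  expect_identical(agreement_band(-0.2, "kappa"), "no agreement")
  expect_identical(agreement_band(0.41, "kappa"), "moderate")
  expect_identical(agreement_band(0.81, "kappa"), "almost perfect")
})

test_that("pairwise agreement covers every operator pair of a measurement table", {
  meas <- expand.grid(operator = 1:3, subject = sprintf("S%02d", 1:8),
                      scan_index = 1:2)
  set.seed(3)
  true_prod <- runif(nrow(meas), 4, 12)
  meas$product_cm2 <- true_prod * exp(rnorm(nrow(meas), 0, 0.1))
  calls <- meas
  calls$call <- as.integer(calls$product_cm2 > 8)
  out <- pairwise_agreement(meas, calls)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$n_pairs == 16))
  expect_true(all(is.finite(out$kappa)))
})
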