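# Timing-based confusion, binary-predictor ROC, DeLong comparison and
# diagnosis-delay analysis.

test_that("first detection returns the earliest positive call and validates ordering", {
  expect_equal(first_detection(c(0, 0.5, 1, 1.5), c(0, 0, 1, 1)), 1.0)
  expect_true(is.na(first_detection(c(0, 0.5, 1), c(0, 0, 0))))
  expect_equal(first_detection(2.5, 1), 2.5)
  expect_error(first_detection(c(1, 0.5), c(0, 1)), "increasing")
})

test_that("timing categories follow detection priority, with 'never' as the limit of 'later'", {
  t_test <- c(1.0, 2.0, NA,  NA, 1.0, 1.5)
  t_ref  <- c(1.0, 1.0, 1.5, NA, 2.0, NA)
  conf <- subject_confusion(t_test, t_ref)
  expect_identical(unname(conf$category),
                   c("tp", "fn", "fn", "tn", "fp", "fp"))
  expect_identical(sum(conf$counts), conf$n)
  expect_equal(conf$overall_accuracy,
               conf$percent[["tn"]] + conf$percent[["tp"]])
  expect_error(subject_confusion(c(1, 2), c(1, 2, 3)), "different subjects")
})

test_that("identical detection times everywhere give 100% accuracy", {
  t <- c(1, 1.5, NA, 2)
  expect_equal(subject_confusion(t, t)$overall_accuracy, 100)
})

test_that("confusion percentages sum to 100 within rounding on random cohorts", {
  set.seed(10)
  for (i in seq_len(20)) {
    n <- sample(20:80, 1)
    t_test <- ifelse(runif(n) < 0.3, NA, sample(seq(0.5, 3, 0.5), n, TRUE))
    t_ref <- ifelse(runif(n) < 0.3, NA, sample(seq(0.5, 3, 0.5), n, TRUE))
    conf <- subject_confusion(t_test, t_ref)
    expect_lt(abs(sum(conf$percent) - 100), 0.03)
    expect_equal(conf$overall_accuracy,
                 conf$percent[["tn"]] + conf$percent[["tp"]], tolerance = 1e-9)
  }
})

test_that("binary ROC equals (sens + spec)/2 and the rank-statistic AUC", {
  set.seed(23)
  for (i in seq_len(20)) {
    n <- sample(20:60, 1)
    outcome <- rbinom(n, 1, 0.5)
    if (length(unique(outcome)) < 2) next
    pred <- ifelse(runif(n) < 0.7, outcome, rbinom(n, 1, 0.5))
    r <- binary_roc(pred, outcome)
    expect_equal(r$auc, (r$sensitivity + r$specificity) / 2)
    expect_equal(r$auc, oracle_rank_auc(pred, outcome))
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  }
})

test_that("perfect and random binary predictors bracket the AUC scale", {
  outcome <- rep(c(0, 1), each = 25)
  perfect <- binary_roc(outcome, outcome)
  expect_equal(perfect$auc, 1)

  set.seed(91)
  n <- 10000
  outcome <- rbinom(n, 1, 0.5)
  pred <- rbinom(n, 1, 0.5)
  r <- binary_roc(pred, outcome)
  expect_lt(abs(r$auc - 0.5), 3 * r$se_auc)
  expect_error(binary_roc(rep(1, 10), rep(1, 10)), "both classes")
})

test_that("DeLong comparison: identical predictors give p = 1, opposite ones p < 0.001", {
  set.seed(6)
  n <- 400
  outcome <- rbinom(n, 1, 0.5)
  pred <- ifelse(runif(n) < 0.8, outcome, 1 - outcome)
  ra <- binary_roc(pred, outcome)
  same <- compare_rocs(ra, binary_roc(pred, outcome))
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)

  rb <- binary_roc(1 - pred, outcome)
  opp <- compare_rocs(ra, rb)
  expect_lt(opp$p_value, 0.001)
  expect_error(compare_rocs(ra, binary_roc(pred[-1], outcome[-1])), "paired")
})

test_that("DeLong p-values are roughly uniform under equal AUCs", {
  set.seed(14)
  ps <- replicate(60, {
    n <- 150
    signal <- rbinom(n, 1, 0.5)
    pa <- ifelse(runif(n) < 0.75, signal, 1 - signal)
    pb <- ifelse(runif(n) < 0.75, signal, 1 - signal)
    compare_rocs(binary_roc(pa, signal), binary_roc(pb, signal))$p_value
  })
  # no mass pile-up at the tails: median within [0.25, 0.75], >20% above 0.5
  expect_gt(stats::median(ps), 0.25)
  expect_lt(stats::median(ps), 0.75)
  expect_gt(mean(ps > 0.5), 0.2)
})

test_that("delay analysis reproduces hand-built medians and flags empty sides", {
  # two FN subjects with delays 2.0 and 2.1; one FP with delay 0.5
  t_ref <- c(1.0, 1.0, 2.0)
  t_test <- c(3.0, 3.1, 1.5)
  d <- delay_analysis(t_test, t_ref)
  expect_equal(sort(d$fn_delays), c(2.0, 2.1))
  expect_equal(d$fp_delays, 0.5)
  expect_equal(d$median_fn_delay, 2.05)
  expect_equal(d$median_fp_delay, 0.50)
  expect_true(all(c(d$fn_delays, d$fp_delays) >= 0))

  same <- delay_analysis(c(1, 2), c(1, 2))
  expect_identical(length(same$fn_delays), 0L)
  expect_identical(length(same$fp_delays), 0L)
  expect_true(is.na(same$p_value))
  expect_match(same$note, "empty")
})

test_that("subjects with a never-detecting arm are excluded from delays but counted", {
  t_ref <- c(1.0, 1.0, NA)
  t_test <- c(NA, 2.0, 1.0)   # FN without delay, FN with delay, FP without delay
  d <- delay_analysis(t_test, t_ref)
  expect_equal(d$fn_delays, 1.0)
  expect_identical(d$n_fn_excluded, 1L)
  expect_identical(d$n_fp_excluded, 1L)
})

test_that("printed-percentage reconstruction yields integer counts and accuracies", {
  vis_prev <- confusion_from_percent(14.29, 19.05, 39.68, 26.98, n = 63)
  expect_identical(unname(vis_prev$counts), c(9, 12, 25, 17))
  expect_equal(vis_prev$overall_accuracy, 66.67)
  vol_base <- confusion_from_percent(9.68, 33.87, 16.13, 40.32, n = 62)
  expect_identical(unname(vol_base$counts), c(6, 21, 10, 25))
  expect_error(confusion_from_percent(50, 30, 10, 5), "sum to 100")
})
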