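# Subject-level timing-based confusion analysis, binary-classifier ROC/AUC
# (with AUC-vs-0.5 testing, Youden operating point and paired DeLong ROC
# comparison) and diagnosis-delay analysis of a test method against a
# reference standard.
#
# Confusion semantics are timing-based, per subject: a false negative means
# the reference standard detected growth before the test method; a false
# positive means the test detected growth first; true negative means
# neither detected; true positive means both detected at the same scan.
# "Never detects" is the limit of "later": it maps to FN or FP when the
# other arm detects, and to TN only when both never detect.

#' First detection time in an ordered growth-call sequence
#'
#' @param times Strictly increasing scan times.
#' @param calls Binary growth calls, one per time.
#' @return The earliest time with `call = 1`, or `NA` when growth is never
#'   called.
#' @export
first_detection <- function(times, calls) {
  stopifnot(length(times) == length(calls), all(calls %in% c(0, 1)))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing (unordered input rejected)")
  hit <- which(calls == 1)
  if (length(hit) == 0L) NA_real_ else times[hit[1L]]
}

# per-subject timing category; NA detection time = never detects
confusion_category <- function(t_test, t_ref) {
  if (is.na(t_test) && is.na(t_ref)) return("tn")
  if (is.na(t_test)) return("fn")                 # reference detected, test never
  if (is.na(t_ref)) return("fp")                  # test detected, reference never
  if (t_test == t_ref) return("tp")
  if (t_test > t_ref) "fn" else "fp"
}

#' Subject-level timing confusion summary
#'
#' Compares per-subject first-detection times of a test method against a
#' reference standard and tabulates the four timing categories (see the
#' module notes above). Percentages are reported to 2 decimals and the
#' overall accuracy is their identity `TN% + TP%`.
#'
#' @param t_test,t_ref Named or positionally aligned vectors of per-subject
#'   detection times (`NA` = never detects); must cover the same subjects.
#' @return An object of class `confusion_summary`: `counts` (fn, fp, tn,
#'   tp), `n`, `percent` (2-decimal percentages), `overall_accuracy`
#'   (`= tn% + tp%`), and `category` (per-subject labels).
#' @export
subject_confusion <- function(t_test, t_ref) {
  if (length(t_test) != length(t_ref))
    stop("test and reference arms cover different subjects")
  if (!is.null(names(t_test)) && !is.null(names(t_ref))) {
    if (!setequal(names(t_test), names(t_ref)))
      stop("test and reference arms cover different subjects")
    t_ref <- t_ref[names(t_test)]
  }
  cat_i <- mapply(confusion_category, t_test, t_ref)
  counts <- vapply(c("fn", "fp", "tn", "tp"), function(k) sum(cat_i == k),
                   integer(1))
  n <- length(t_test)
  percent <- round(100 * counts / n, 2)
  structure(list(counts = counts, n = n, percent = percent,
                 overall_accuracy = unname(percent[["tn"]] + percent[["tp"]]),
                 category = cat_i),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Timing confusion over %d subjects: FN %.2f%%, FP %.2f%%, TN %.2f%%, TP %.2f%% | accuracy %.2f%%\n",
              x$n, x$percent[["fn"]], x$percent[["fp"]], x$percent[["tn"]],
              x$percent[["tp"]], x$overall_accuracy))
  invisible(x)
}

#' Confusion summary from printed percentages
#'
#' Rebuilds a summary from the four category percentages of a published
#' table; the overall accuracy is the `TN% + TP%` identity.
#'
#' @param fn,fp,tn,tp Category percentages (must sum to 100 within
#'   rounding).
#' @param n Optional subject count; when given, the implied counts
#'   `percent * n / 100` must be integers within `tol` and are returned, and
#'   the overall accuracy is recomputed from those counts (the printed
#'   `TN% + TP%` can be off by 0.01 from rounding of the category
#'   percentages).
#' @param tol Tolerance for the integer reconstruction (default 0.05).
#' @return A list: `percent`, `overall_accuracy` (2 decimals), and (when `n`
#'   is given) `counts` and `n`.
#' @export
confusion_from_percent <- function(fn, fp, tn, tp, n = NULL, tol = 0.05) {
  pct <- c(fn = fn, fp = fp, tn = tn, tp = tp)
  if (abs(sum(pct) - 100) > 0.05)
    stop("category percentages must sum to 100 (within rounding)")
  out <- list(percent = pct, overall_accuracy = unname(tn + tp))
  if (!is.null(n)) {
    raw <- pct * n / 100
    counts <- round(raw)
    if (any(abs(raw - counts) > tol))
      stop("percentages do not reconstruct integer counts at n = ", n)
    out$counts <- counts
    out$n <- as.integer(n)
    out$overall_accuracy <- round(100 * (counts[["tn"]] + counts[["tp"]]) / n, 2)
  }
  out
}

#' ROC analysis of a binary predictor
#'
#' For a dichotomous predictor the ROC curve has a single interior operating
#' point, so `AUC = (sensitivity + specificity) / 2`, which equals the
#' rank-statistic (concordance) AUC. The AUC standard error uses the
#' one-curve DeLong variance and is tested against 0.5 (random agreement);
#' the Youden-optimal cutoff for a 0/1 predictor is the predictor itself
#' (operating cutoff 0.5).
#'
#' @param pred Binary 0/1 predictions.
#' @param outcome Binary 0/1 ground-truth outcomes (both classes present).
#' @return An object of class `roc_result`: `auc`, `se_auc`, `p_vs_half`
#'   (two-sided), `sensitivity`, `specificity`, `youden`, `youden_cutoff`,
#'   `n`, plus the underlying `pROC::roc` object (`roc`) for curve
#'   comparison.
#' @export
binary_roc <- function(pred, outcome) {
  stopifnot(length(pred) == length(outcome),
            all(pred %in% c(0, 1)), all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2L)
    stop("outcome must contain both classes")
  sens <- sum(pred == 1 & outcome == 1) / sum(outcome == 1)
  spec <- sum(pred == 0 & outcome == 0) / sum(outcome == 0)
  auc <- (sens + spec) / 2
  r <- pROC::roc(response = outcome, predictor = pred, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  # a degenerate (perfect) curve has zero DeLong variance; pROC warns
  se <- sqrt(suppressWarnings(pROC::var(r)))
  if (!is.finite(se)) se <- 0
  p <- if (se > 0) 2 * stats::pnorm(abs(auc - 0.5) / se, lower.tail = FALSE)
       else if (abs(auc - 0.5) < 1e-12) 1 else 0
  structure(list(auc = auc, se_auc = se, p_vs_half = p,
                 sensitivity = sens, specificity = spec,
                 youden = sens + spec - 1, youden_cutoff = 0.5,
                 n = length(outcome), pred = pred, outcome = outcome,
                 roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Binary ROC: AUC = %.3f +/- %.3f (p vs 0.5 = %s), sens = %.3f, spec = %.3f, n = %d\n",
              x$auc, x$se_auc, format.pval(x$p_vs_half, digits = 3),
              x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Compare two paired ROC analyses (DeLong)
#'
#' Paired covariance-adjusted z-test on the AUC difference of two predictors
#' evaluated on the same subjects and outcome. Identical predictors give a
#' difference of 0 and p = 1.
#'
#' @param roc_a,roc_b `roc_result` objects from [binary_roc()] on the same
#'   outcome vector.
#' @return A list: `auc_diff`, `p_value`, `method`.
#' @export
compare_rocs <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (roc_a$n != roc_b$n || !all(roc_a$outcome == roc_b$outcome))
    stop("ROC comparison requires a paired design (same subjects and outcome)")
  diff <- roc_a$auc - roc_b$auc
  if (all(roc_a$pred == roc_b$pred))
    return(list(auc_diff = 0, p_value = 1, method = "DeLong paired (identical predictors)"))
  tst <- pROC::roc.test(roc_a$roc, roc_b$roc, method = "delong", paired = TRUE)
  p <- tst$p.value
  if (!is.finite(p)) p <- if (abs(diff) < 1e-12) 1 else NA_real_
  list(auc_diff = diff, p_value = p, method = "DeLong paired")
}

#' Diagnosis-delay analysis of a test method against a reference standard
#'
#' Over false-negative subjects (reference first), the delay is
#' `t_test - t_ref`; over false-positive subjects (test first), it is
#' `t_ref - t_test`; both are non-negative by construction. Subjects where
#' either arm never detects carry no finite delay and are excluded (their
#' count is reported). Medians are compared with a rank-based two-sample
#' test (Wilcoxon).
#'
#' @inheritParams subject_confusion
#' @return An object of class `delay_result`: `median_fn_delay`,
#'   `median_fp_delay` (years), `p_value` (`NA` with a `note` when either
#'   side is empty), `fn_delays`, `fp_delays`, `n_fn_excluded`,
#'   `n_fp_excluded`, `test_method`.
#' @export
delay_analysis <- function(t_test, t_ref) {
  conf <- subject_confusion(t_test, t_ref)
  cat_i <- conf$category
  fn_all <- which(cat_i == "fn")
  fp_all <- which(cat_i == "fp")
  fn_ok <- fn_all[!is.na(t_test[fn_all]) & !is.na(t_ref[fn_all])]
  fp_ok <- fp_all[!is.na(t_test[fp_all]) & !is.na(t_ref[fp_all])]
  fn_delays <- unname(t_test[fn_ok] - t_ref[fn_ok])
  fp_delays <- unname(t_ref[fp_ok] - t_test[fp_ok])
  note <- NULL
  if (length(fn_delays) >= 1L && length(fp_delays) >= 1L) {
    p <- stats::wilcox.test(fn_delays, fp_delays, exact = FALSE)$p.value
  } else {
    p <- NA_real_
    note <- "p not computable: empty delay set on one side"
  }
  structure(list(median_fn_delay = stats::median(fn_delays),
                 median_fp_delay = stats::median(fp_delays),
                 p_value = p,
                 fn_delays = fn_delays, fp_delays = fp_delays,
                 n_fn_excluded = length(fn_all) - length(fn_ok),
                 n_fp_excluded = length(fp_all) - length(fp_ok),
                 test_method = "Wilcoxon rank-sum", note = note),
            class = "delay_result")
}

#' @export
print.delay_result <- function(x, ...) {
  cat(sprintf("Delay analysis: median FN delay %.2f yr (n=%d) vs FP %.2f yr (n=%d), %s p = %s\n",
              x$median_fn_delay, length(x$fn_delays),
              x$median_fp_delay, length(x$fp_delays),
              x$test_method, format.pval(x$p_value, digits = 3)))
  invisible(x)
}
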