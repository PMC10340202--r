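# Reproducibility statistics for paired operator measurement sets: Pearson
# regression agreement with interpretation bands, a between-operator
# coefficient of variance, Bland-Altman percent differences with 95% limits
# of agreement, and Cohen's kappa for dichotomized growth calls.

#' Interpretation band for an agreement coefficient
#'
#' Correlation-agreement bands: poor (<= 0), slight (0.01-0.20), fair
#' (0.21-0.40), moderate (0.41-0.60), good (0.61-0.80), excellent
#' (0.81-1.00). Kappa bands: no agreement (<= 0), none-to-slight, fair,
#' moderate, substantial, almost perfect over the same cut points. Upper
#' edges are inclusive.
#'
#' @param value Coefficient value.
#' @param type `"correlation"` or `"kappa"`.
#' @return Band label (character).
#' @export
agreement_band <- function(value, type = c("correlation", "kappa")) {
  type <- match.arg(type)
  labels <- if (type == "correlation")
    c("poor", "slight", "fair", "moderate", "good", "excellent")
  else
    c("no agreement", "none to slight", "fair", "moderate", "substantial",
      "almost perfect")
  if (is.na(value)) return(NA_character_)
  cuts <- c(0, 0.20, 0.40, 0.60, 0.80, 1.00)
  labels[findInterval(value, cuts, left.open = TRUE) + 1L]
}

#' Pearson regression agreement between paired measurements
#'
#' Reports the squared Pearson correlation (`r2`) with its interpretation
#' band, a between-operator coefficient of variance, and the Bland-Altman
#' percent-difference summary. The CV here is
#' `100 * SD(x - y) / mean(c(x, y))`: the SD of paired differences relative
#' to the pooled mean, a between-operator variability measure (the formula
#' is recorded in the result's `cv_formula` field so alternative definitions
#' stay pluggable).
#'
#' @param x,y Paired positive measurements (same length, >= 3 pairs).
#' @param denominator Percent-difference denominator for the Bland-Altman
#'   component, see [bland_altman()].
#' @return An object of class `agreement_report`: `r2`, `cv_percent`,
#'   `mean_percent_diff`, `loa_low`, `loa_high`, `n_pairs`,
#'   `interpretation`, `cv_formula`. Zero-variance input yields `r2 = NA`
#'   (undefined, not 0) with a `note`.
#' @export
regression_agreement <- function(x, y, denominator = c("pair_mean", "first")) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs")
  note <- NULL
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r2 <- NA_real_
    note <- "r2 undefined: zero-variance input"
  } else {
    r2 <- stats::cor(x, y)^2
  }
  cv <- 100 * stats::sd(x - y) / mean(c(x, y))
  ba <- bland_altman(x, y, denominator = denominator)
  structure(list(r2 = r2, cv_percent = cv,
                 mean_percent_diff = ba$mean_percent_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 n_pairs = length(x),
                 interpretation = agreement_band(r2, "correlation"),
                 cv_formula = "100 * sd(x - y) / mean(c(x, y))",
                 note = note),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs: r2 = %s (%s), CV = %.1f%%, diff = %.1f%% [%.1f, %.1f]\n",
              x$n_pairs, ifelse(is.na(x$r2), "undefined", sprintf("%.3f", x$r2)),
              ifelse(is.na(x$interpretation), "-", x$interpretation),
              x$cv_percent, x$mean_percent_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman percent-difference analysis
#'
#' Per-pair percent difference `100 * (x - y) / denominator` with the pair
#' mean `(x + y) / 2` as the default denominator (the first measurement is
#' selectable); reports the mean difference and the 95% limits of agreement
#' `mean +/- 1.96 * SD`. Pairs with zero denominator are excluded and
#' counted.
#'
#' @param x,y Paired positive measurements.
#' @param denominator `"pair_mean"` (default) or `"first"`.
#' @return A list: `mean_percent_diff`, `loa_low`, `loa_high`, `sd_percent`,
#'   `n_pairs`, `n_excluded`, `denominator`.
#' @export
bland_altman <- function(x, y, denominator = c("pair_mean", "first")) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  denominator <- match.arg(denominator)
  den <- if (denominator == "pair_mean") (x + y) / 2 else x
  ok <- den > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(sprintf("bland_altman: excluded %d pair(s) with non-positive denominator", n_excluded))
  pd <- 100 * (x[ok] - y[ok]) / den[ok]
  m <- mean(pd)
  s <- if (length(pd) > 1L) stats::sd(pd) else 0
  list(mean_percent_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_percent = s, n_pairs = sum(ok), n_excluded = n_excluded,
       denominator = denominator)
}

#' Cohen's kappa for paired categorical calls
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' raters of the same items, with the large-sample standard error and a
#' one-sided p-value against `kappa = 0` (computed with the null-hypothesis
#' SE of Fleiss). When both raters agree perfectly on a single category
#' (`p_e = 1`, `p_o = 1`), kappa is 1 by convention.
#'
#' @param a,b Vectors of paired calls (equal length, n >= 2); any discrete
#'   coding works, growth calls are 0/1.
#' @return An object of class `kappa_result`: `kappa`, `se` (large-sample),
#'   `p_value` (one-sided vs 0), `interpretation` (kappa band), `p_o`,
#'   `p_e`, `n`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("rater vectors differ in length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired calls")
  levels_all <- sort(unique(c(a, b)))
  a <- factor(a, levels = levels_all)
  b <- factor(b, levels = levels_all)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  pr <- rowSums(tab)
  pc <- colSums(tab)
  p_e <- sum(pr * pc)
  if (p_e >= 1 - 1e-12) {
    kap <- if (p_o >= 1 - 1e-12) 1 else NA_real_
    return(structure(list(kappa = kap, se = 0, p_value = NA_real_,
                          interpretation = agreement_band(kap, "kappa"),
                          p_o = p_o, p_e = p_e, n = n),
                     class = "kappa_result"))
  }
  kap <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o)) / ((1 - p_e) * sqrt(n))   # large-sample SE
  se0 <- sqrt(p_e + p_e^2 - sum(pr * pc * (pr + pc))) / ((1 - p_e) * sqrt(n))
  p <- stats::pnorm(kap / se0, lower.tail = FALSE)
  structure(list(kappa = kap, se = se, p_value = p,
                 interpretation = agreement_band(kap, "kappa"),
                 p_o = p_o, p_e = p_e, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f +/- %.3f (%s), one-sided p vs 0 = %s, n = %d\n",
              x$kappa, x$se, x$interpretation,
              format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' Pairwise operator agreement report
#'
#' Runs [regression_agreement()] on every operator pair of a measurement
#' table (long format, as produced by the measurement stage) and
#' [cohens_kappa()] on every pair of a call table.
#'
#' @param measurements Data frame with columns `operator`, `subject`,
#'   `scan_index`, `product_cm2`.
#' @param calls Optional data frame with `operator`, `subject`,
#'   `scan_index`, `call` (0/1) for the kappa block.
#' @return A data frame with one row per operator pair: `operator_a`,
#'   `operator_b`, `n_pairs`, `r2`, `cv_percent`, `mean_percent_diff`,
#'   `loa_low`, `loa_high`, and (when `calls` is given) `kappa`, `kappa_p`.
#' @export
pairwise_agreement <- function(measurements, calls = NULL) {
  ops <- sort(unique(measurements$operator))
  if (length(ops) < 2L) stop("need at least 2 operators")
  key <- function(df) paste(df$subject, df$scan_index)
  rows <- list()
  for (i in seq_along(ops)) for (j in seq_along(ops)) {
    if (i >= j) next
    ma <- measurements[measurements$operator == ops[i], ]
    mb <- measurements[measurements$operator == ops[j], ]
    mb <- mb[match(key(ma), key(mb)), ]
    rep <- regression_agreement(ma$product_cm2, mb$product_cm2)
    row <- data.frame(operator_a = ops[i], operator_b = ops[j],
                      n_pairs = rep$n_pairs, r2 = rep$r2,
                      cv_percent = rep$cv_percent,
                      mean_percent_diff = rep$mean_percent_diff,
                      loa_low = rep$loa_low, loa_high = rep$loa_high)
    if (!is.null(calls)) {
      ca <- calls[calls$operator == ops[i], ]
      cb <- calls[calls$operator == ops[j], ]
      cb <- cb[match(key(ca), key(cb)), ]
      kp <- cohens_kappa(ca$call, cb$call)
      row$kappa <- kp$kappa
      row$kappa_p <- kp$p_value
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
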