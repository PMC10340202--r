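# Slice-stack volumetrics and change-of-point growth detection: the 3D arm
# of the pipeline. Volume is the sum of per-slice foreground areas times the
# center-to-center inter-slice distance; unlike the bidimensional
# measurement, it is additive over disjoint components, so satellite lesions
# are counted.

#' Tumor volume of a mask stack
#'
#' `volume = (sum of per-slice foreground areas) x inter-slice distance`,
#' returned in cm^3. An empty mask has volume 0.
#'
#' @param label A [label_volume]; its geometry must carry the inter-slice
#'   distance (never silently replaced by the slice thickness).
#' @return Volume in cm^3.
#' @export
compute_volume <- function(label) {
  stopifnot(inherits(label, "label_volume"))
  acq <- label$geometry
  if (is.null(acq$inter_slice_distance) || !is.finite(acq$inter_slice_distance))
    stop("inter-slice distance missing from geometry")
  area_mm2 <- sum(label$mask) * acq$in_plane_spacing^2
  area_mm2 * acq$inter_slice_distance / 1000
}

#' Per-subject longitudinal volume series
#'
#' @param subject Subject identifier.
#' @param times Strictly increasing scan times, years.
#' @param volumes Non-negative volumes, cm^3, one per time.
#' @return An object of class `volume_series` with `change_time = NA` until
#'   [detect_change_point()] is applied.
#' @export
volume_series <- function(subject, times, volumes) {
  stopifnot(length(times) == length(volumes), all(volumes >= 0))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(subject = subject, times = as.numeric(times),
                 volumes = as.numeric(volumes),
                 change_time = NA_real_, change_index = NA_integer_,
                 alpha = NA_real_),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("Volume series %s: %d scans over %.1f yr; change at %s\n",
              format(x$subject), length(x$times), diff(range(x$times)),
              if (is.na(x$change_time)) "none" else
                sprintf("%.2f yr", x$change_time)))
  invisible(x)
}

#' Detect the first significant volume increase in a series
#'
#' Scans forward through the series and, at each candidate scan `k` with at
#' least `min_prior` earlier scans, fits a constant-mean noise model to all
#' prior volumes (mean `m`, SD `s`, floored at `sd_floor_frac * m`) and tests
#' whether the current volume exceeds the one-sided upper prediction bound
#'
#' `m + t(1 - alpha, df = k_prior - 1) * s * sqrt(1 + 1/k_prior)`.
#'
#' Growth is declared at the earliest `k` whose exceedance persists at the
#' next scan (tested against the same bound). The last scan of the series
#' has no confirming follow-up, so it is exempt from the persistence check
#' but tested at the stricter level `terminal_alpha` (default `alpha / 2`):
#' this alpha-spending keeps the family-wise false-trigger rate of the whole
#' scan near the nominal `alpha`. Detection is one-sided: only increases
#' count. The procedure is scale-equivariant - multiplying all volumes by a
#' positive constant leaves the detected scan unchanged.
#'
#' @param series A [volume_series] with at least `min_prior + 1` points.
#' @param alpha One-sided significance level (default 0.05).
#' @param min_prior Minimum number of prior scans before testing (default 3,
#'   mirroring the at-least-4-scans inclusion rule).
#' @param sd_floor_frac Floor on the prior-scan SD as a fraction of the prior
#'   mean (default 0.05), guarding against degenerate noiseless runs.
#' @param persistence If `TRUE` (default) a non-terminal exceedance must be
#'   confirmed at the following scan.
#' @param terminal_alpha Significance level for the persistence-exempt final
#'   scan (default `alpha / 2`; ignored when `persistence = FALSE`).
#' @return The input series with `change_time` (years; `NA` when never
#'   triggered), `change_index` and `alpha` filled in.
#' @export
detect_change_point <- function(series, alpha = 0.05, min_prior = 3L,
                                sd_floor_frac = 0.05, persistence = TRUE,
                                terminal_alpha = alpha / 2) {
  stopifnot(inherits(series, "volume_series"), alpha > 0, alpha < 1,
            min_prior >= 2L)
  v <- series$volumes
  n <- length(v)
  if (n < min_prior + 1L)
    stop(sprintf("insufficient series: %d scans, need at least %d", n, min_prior + 1L))
  series$alpha <- alpha
  for (k in (min_prior + 1L):n) {
    prior <- v[seq_len(k - 1L)]
    m <- mean(prior)
    s <- max(stats::sd(prior), sd_floor_frac * m)
    a_k <- if (persistence && k == n) terminal_alpha else alpha
    bound <- m + stats::qt(1 - a_k, df = k - 2L) * s * sqrt(1 + 1 / (k - 1L))
    if (v[k] > bound) {
      confirmed <- (k == n) || !persistence || (v[k + 1L] > bound)
      if (confirmed) {
        series$change_index <- k
        series$change_time <- series$times[k]
        return(series)
      }
    }
  }
  series
}

#' Build and test volume series for a generated cohort
#'
#' Convenience wrapper: computes [compute_volume()] for every scan of every
#' subject and applies [detect_change_point()].
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param ... Passed to [detect_change_point()].
#' @return A data frame with one row per subject x scan (`subject`,
#'   `scan_index`, `time`, `volume_cm3`, `change_time`).
#' @export
cohort_volume_series <- function(cohort, ...) {
  out <- lapply(cohort, function(subj) {
    vols <- vapply(subj$scans, function(s) compute_volume(s$label), numeric(1))
    times <- vapply(subj$scans, function(s) s$label$scan_time, numeric(1))
    ser <- detect_change_point(volume_series(subj$subject, times, vols), ...)
    data.frame(subject = subj$subject, scan_index = seq_along(vols),
               time = times, volume_cm3 = vols,
               change_time = ser$change_time)
  })
  do.call(rbind, out)
}
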