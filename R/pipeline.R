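# End-to-end pipeline: simulate a longitudinal cohort, measure it with
# simulated operators under the bidimensional rule, run the volumetric
# change-of-point arm and a synthetic visual arm, and evaluate agreement,
# timing confusion, ROC and diagnosis delay. Every random draw derives from
# the single configured seed, so identical configurations give identical
# reports.

#' Default pipeline configuration
#'
#' A nested list covering cohort composition, acquisition geometry, operator
#' noise, engine thresholds, change-point parameters, the synthetic visual
#' arm, segmentation options and output switches. See the methods vignette
#' for the rationale behind each default.
#'
#' @return A named nested list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 101L,
    cohort = list(
      n_subjects = 60L,
      n_scans = 8L,
      scan_interval_years = 0.5,
      frac_stable = 0.4,          # stable trajectories
      frac_inplane = 0.25,        # isotropic growers (visible to RANO)
      frac_occult = 0.35,         # satellite / out-of-plane growers
      baseline_radii = c(18, 14, 10),
      radii_jitter_frac = 0.15,
      growth_rate_inplane = 0.45,
      growth_rate_occult = 0.35,
      occult_main_rate = 0.12,    # slow in-plane creep of occult growers
      occult_satellite_frac = 0.5,# of occult growers; rest grow out of plane
      satellite_count = 2L,
      satellite_radius = 4,
      margin_irregularity = 0.1,
      change_scan_min = 2L,       # last pre-growth scan index, sampled
      change_scan_max = 4L),
    acquisition = list(
      in_plane_spacing = 1,
      slice_thickness = 5,
      inter_slice_distance = 6.5,
      grid_shape = c(32L, 128L, 128L)),
    operators = list(n_operators = 3L, inter_sd_frac = 0.15,
                     intra_sd_frac = 0.05),
    visual = list(threshold = 0.25, noise_sd_frac = 0.1),
    engine = list(growth_threshold = 0.25, inclusive = TRUE,
                  perp_tol_deg = 5, consensus_k = 2L),
    changepoint = list(alpha = 0.05, min_prior = 3L, sd_floor_frac = 0.05),
    segmentation = list(enabled = FALSE, k = 8L, n_bins = 8L,
                        gray_level = NULL, noise_sd = 5),
    output = list(write_volumes = FALSE)
  )
}

merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(overrides[[key]]))
        stop("configuration key ", full, " must be a list")
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]], full)
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Merges overrides into [default_pipeline_config()]; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param overrides A named (possibly nested) list of overrides, or the path
#'   of a YAML file containing one.
#' @return The resolved configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1L)
    overrides <- yaml::read_yaml(overrides)
  cfg <- merge_config(default_pipeline_config(), overrides)
  fr <- cfg$cohort[c("frac_stable", "frac_inplane", "frac_occult")]
  if (abs(sum(unlist(fr)) - 1) > 1e-6)
    stop("cohort fractions must sum to 1")
  cfg
}

# Build the per-subject trajectory specs implied by a configuration.
build_trajectory_specs <- function(cfg, seed) {
  set.seed(seed)
  co <- cfg$cohort
  n <- co$n_subjects
  n_stable <- round(co$frac_stable * n)
  n_inplane <- round(co$frac_inplane * n)
  n_occult <- n - n_stable - n_inplane
  kinds <- sample(c(rep("stable", n_stable), rep("inplane", n_inplane),
                    rep("occult", n_occult)))
  times <- seq(0, by = co$scan_interval_years, length.out = co$n_scans)
  lapply(kinds, function(kind) {
    radii <- co$baseline_radii *
      (1 + stats::runif(3, -co$radii_jitter_frac, co$radii_jitter_frac))
    change <- sample(co$change_scan_min:co$change_scan_max, 1)
    if (kind == "stable") {
      trajectory_spec(radii, "stable", scan_times = times,
                      margin_irregularity = co$margin_irregularity)
    } else if (kind == "inplane") {
      trajectory_spec(radii, "change_point", change_time = change,
                      growth_rate = co$growth_rate_inplane,
                      scan_times = times, growth_site = "isotropic",
                      margin_irregularity = co$margin_irregularity)
    } else if (stats::runif(1) < co$occult_satellite_frac) {
      trajectory_spec(radii, "change_point", change_time = change,
                      growth_rate = co$growth_rate_occult,
                      satellite_count = co$satellite_count,
                      satellite_radius = co$satellite_radius,
                      scan_times = times, growth_site = "satellite",
                      main_growth_rate = co$occult_main_rate,
                      margin_irregularity = co$margin_irregularity)
    } else {
      trajectory_spec(radii, "change_point", change_time = change,
                      growth_rate = co$growth_rate_occult,
                      scan_times = times, growth_site = "out_of_plane",
                      margin_irregularity = co$margin_irregularity)
    }
  })
}

# Measure every scan of a subject with every operator; returns measurement
# rows (one per operator x scan) and the true measurements.
measure_subject <- function(subj, cfg, model, biases, seed) {
  n_scans <- length(subj$scans)
  truth <- lapply(subj$scans, function(s)
    rano_measure(s$label, perp_tol_deg = cfg$engine$perp_tol_deg))
  rows <- lapply(seq_len(n_scans), function(k) {
    reads <- simulate_operator_reads(truth[[k]], model, biases = biases,
                                     seed = seed + k)
    data.frame(subject = subj$subject, scan_index = k,
               time = subj$scans[[k]]$label$scan_time, reads)
  })
  list(table = do.call(rbind, rows), truth = truth)
}

# Per-operator growth calls (previous / baseline referencing) from a
# measurement table of one subject, plus the consensus call per scan.
call_growth <- function(meas, cfg) {
  eng <- cfg$engine
  rows <- list()
  for (op in unique(meas$operator)) {
    mo <- meas[meas$operator == op, ]
    mo <- mo[order(mo$scan_index), ]
    for (k in 2:nrow(mo)) {
      for (ref in c("previous", "baseline")) {
        ref_prod <- if (ref == "previous") mo$product_cm2[k - 1]
                    else mo$product_cm2[1]
        g <- classify_growth(mo$product_cm2[k], ref_prod,
                             threshold = eng$growth_threshold,
                             inclusive = eng$inclusive)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = mo$subject[1], scan_index = mo$scan_index[k],
          time = mo$time[k], operator = op, reference = ref,
          percent_change = g$percent_change, call = g$call)
      }
    }
  }
  calls <- do.call(rbind, rows)
  agg <- stats::aggregate(call ~ subject + scan_index + time + reference,
                          data = calls,
                          FUN = function(x) consensus_call(x, k = eng$consensus_k))
  list(calls = calls, consensus = agg[order(agg$reference, agg$scan_index), ])
}

# Synthetic visual arm: operators judge growth from the true volume change
# with multiplicative perception noise, then 2-of-n consensus.
visual_calls <- function(subj, cfg, seed) {
  vis <- cfg$visual
  n_ops <- cfg$operators$n_operators
  n_scans <- length(subj$true_volumes_cm3)
  set.seed(seed)
  rows <- list()
  for (k in 2:n_scans) {
    for (ref in c("previous", "baseline")) {
      vref <- if (ref == "previous") subj$true_volumes_cm3[k - 1]
              else subj$true_volumes_cm3[1]
      ratio <- subj$true_volumes_cm3[k] / vref
      perceived <- ratio * (1 + stats::rnorm(n_ops, 0, vis$noise_sd_frac))
      calls <- as.integer(perceived >= 1 + vis$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj$subject, scan_index = k,
        time = subj$scans[[k]]$label$scan_time, reference = ref,
        call = consensus_call(calls, k = cfg$engine$consensus_k))
    }
  }
  do.call(rbind, rows)
}

#' Run the full progression-assessment pipeline
#'
#' Simulates a cohort, measures it with simulated operators under the
#' bidimensional 25%-growth rule (previous and baseline referencing,
#' 2-of-3 consensus), runs the volumetric change-of-point arm and the
#' synthetic visual arm, and evaluates: pairwise operator agreement,
#' subject-level timing confusion of the bidimensional arm against each
#' ground truth, scan-level ROC, and diagnosis-delay analysis against the
#' volumetric reference. A failing subject is isolated (recorded under
#' `failures`) and the run continues.
#'
#' @param config A configuration from [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes the cohort
#'   manifest (and volumes when configured), all tables (TSV), the
#'   evaluation report (JSON) and the resolved configuration (YAML).
#' @param cohort Optional pre-generated cohort (from [generate_cohort()] or
#'   [read_cohort()]); when supplied the simulate stage is skipped.
#' @return A list of class `pipeline_report`: `tables` (measurements,
#'   operator calls, consensus calls, visual calls, volume series,
#'   detection times), `agreement`, `evaluation` (per reference mode:
#'   confusion, ROC, DeLong comparison, delay), `failures`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL) {
  set.seed(config$seed)
  seeds <- sample.int(2^30, 6)
  if (is.null(cohort)) {
    specs <- build_trajectory_specs(config, seeds[1])
    acq <- do.call(acquisition_params, config$acquisition)
    cohort <- generate_cohort(specs, acq, seed = seeds[2],
                              render_intensity = config$segmentation$enabled,
                              noise_sd = config$segmentation$noise_sd,
                              on_error = "skip")
  }
  model <- do.call(operator_model, c(config$operators, seed = seeds[3]))
  biases <- operator_biases(model)

  failures <- as.list(attr(cohort, "failures"))
  meas_tables <- list(); call_tables <- list(); cons_tables <- list()
  vis_tables <- list(); seg_tables <- list()
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    res <- tryCatch({
      segs <- NULL
      if (config$segmentation$enabled) {
        subj$scans <- lapply(seq_along(subj$scans), function(k) {
          sc <- subj$scans[[k]]
          gl <- config$segmentation$gray_level
          if (is.null(gl)) gl <- estimate_gray_level(sc$intensity)
          decomp <- decompose_regions(sc$intensity,
                                      k = config$segmentation$k,
                                      n_bins = config$segmentation$n_bins,
                                      seed = seeds[4] + i * 100 + k)
          sc$label <- extract_tumor_mask(decomp, gl,
                                         scan_time = sc$label$scan_time)
          sc$segments <- cbind(subject = subj$subject, scan_index = k,
                               segment_table(decomp))
          sc
        })
        segs <- do.call(rbind, lapply(subj$scans, `[[`, "segments"))
        cohort[[i]] <- subj
      }
      m <- measure_subject(subj, config, model, biases, seeds[4] + i * 1000)
      g <- call_growth(m$table, config)
      v <- visual_calls(subj, config, seeds[5] + i)
      list(meas = m$table, calls = g$calls, cons = g$consensus, vis = v,
           segs = segs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[subj$subject]] <- conditionMessage(res)
      next
    }
    meas_tables[[i]] <- res$meas
    call_tables[[i]] <- res$calls
    cons_tables[[i]] <- res$cons
    vis_tables[[i]] <- res$vis
    seg_tables[[i]] <- res$segs
  }
  if (all(vapply(meas_tables, is.null, logical(1))))
    stop("every subject failed; first error: ", failures[[1]])

  measurements <- do.call(rbind, meas_tables)
  op_calls <- do.call(rbind, call_tables)
  consensus <- do.call(rbind, cons_tables)
  visual <- do.call(rbind, vis_tables)

  volumes <- cohort_volume_series(
    cohort[!vapply(cohort, function(s) s$subject %in% names(failures), logical(1))],
    alpha = config$changepoint$alpha,
    min_prior = config$changepoint$min_prior,
    sd_floor_frac = config$changepoint$sd_floor_frac)

  detection <- detection_table(cohort, consensus, visual, volumes, failures)
  agreement <- pairwise_agreement(
    measurements,
    calls = op_calls[op_calls$reference == "previous", ])
  evaluation <- evaluate_arms(detection, consensus, visual, volumes)

  tables <- list(measurements = measurements, operator_calls = op_calls,
                 consensus_calls = consensus, visual_calls = visual,
                 volume_series = volumes, detection_times = detection)
  if (config$segmentation$enabled)
    tables$segments <- do.call(rbind, seg_tables)
  report <- structure(list(
    tables = tables,
    agreement = agreement,
    evaluation = evaluation,
    failures = failures,
    config = config), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_outputs(report, cohort, out_dir)
  report
}

detection_table <- function(cohort, consensus, visual, volumes, failures) {
  rows <- lapply(cohort, function(subj) {
    id <- subj$subject
    if (id %in% names(failures)) return(NULL)
    det <- function(df) {
      df <- df[df$subject == id, ]
      df <- df[order(df$time), ]
      if (nrow(df) == 0L) NA_real_ else first_detection(df$time, df$call)
    }
    cs <- consensus[consensus$reference == "previous", ]
    cb <- consensus[consensus$reference == "baseline", ]
    vs <- visual[visual$reference == "previous", ]
    vb <- visual[visual$reference == "baseline", ]
    vol <- volumes[volumes$subject == id, ]
    data.frame(subject = id,
               growing = subj$spec$growth_model != "stable",
               growth_site = subj$spec$growth_site,
               true_onset_time = subj$true_onset_time,
               t_rano_previous = det(cs), t_rano_baseline = det(cb),
               t_visual_previous = det(vs), t_visual_baseline = det(vb),
               t_volumetric = vol$change_time[1])
  })
  do.call(rbind, rows)
}

evaluate_arms <- function(detection, consensus, visual, volumes) {
  out <- list()
  for (ref in c("previous", "baseline")) {
    t_rano <- detection[[paste0("t_rano_", ref)]]
    t_vis <- detection[[paste0("t_visual_", ref)]]
    t_vol <- detection$t_volumetric
    names(t_rano) <- names(t_vis) <- names(t_vol) <- detection$subject

    # scan-level ROC: bidimensional consensus call vs each ground truth
    cons_ref <- consensus[consensus$reference == ref, ]
    vis_ref <- visual[visual$reference == ref, ]
    key <- function(df) paste(df$subject, df$scan_index)
    vis_aligned <- vis_ref[match(key(cons_ref), key(vis_ref)), ]
    vol_status <- volumes[match(key(cons_ref), paste(volumes$subject, volumes$scan_index)), ]
    vol_outcome <- as.integer(!is.na(vol_status$change_time) &
                                vol_status$time >= vol_status$change_time)

    roc_visual <- try_roc(cons_ref$call, vis_aligned$call)
    roc_volumetric <- try_roc(cons_ref$call, vol_outcome)
    out[[ref]] <- list(
      confusion_vs_visual = subject_confusion(t_rano, t_vis),
      confusion_vs_volumetric = subject_confusion(t_rano, t_vol),
      roc_vs_visual = roc_visual,
      roc_vs_volumetric = roc_volumetric,
      delay_vs_volumetric = delay_analysis(t_rano, t_vol))
  }
  # DeLong comparison of the two referencing modes against the visual truth
  if (inherits(out$previous$roc_vs_visual, "roc_result") &&
      inherits(out$baseline$roc_vs_visual, "roc_result") &&
      out$previous$roc_vs_visual$n == out$baseline$roc_vs_visual$n &&
      all(out$previous$roc_vs_visual$outcome == out$baseline$roc_vs_visual$outcome)) {
    out$delong_previous_vs_baseline <-
      compare_rocs(out$previous$roc_vs_visual, out$baseline$roc_vs_visual)
  }
  out
}

try_roc <- function(pred, outcome) {
  tryCatch(binary_roc(pred, outcome),
           error = function(e) list(error = conditionMessage(e)))
}

write_pipeline_outputs <- function(report, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  if (isTRUE(cfg$output$write_volumes)) {
    write_cohort(cohort, file.path(out_dir, "volumes"))
  } else {
    # manifest only (no image files)
    man <- do.call(rbind, lapply(cohort, function(subj) {
      data.frame(subject = subj$subject,
                 scan_index = seq_along(subj$scans),
                 time = vapply(subj$scans, function(s) s$label$scan_time, numeric(1)),
                 true_change_index = subj$true_change_index,
                 true_onset_time = subj$true_onset_time,
                 true_volume_cm3 = subj$true_volumes_cm3)
    }))
    write_tsv(man, file.path(out_dir, "manifest.tsv"))
  }
  for (nm in names(report$tables))
    write_tsv(report$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  write_tsv(report$agreement, file.path(out_dir, "agreement.tsv"))
  write_tsv(evaluation_table(report$evaluation),
            file.path(out_dir, "evaluation.tsv"))
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(report$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

# Delimited evaluation summary: one row per reference mode x ground truth,
# mirroring the subject-level confusion-table layout
evaluation_table <- function(evaluation) {
  rows <- list()
  for (ref in c("previous", "baseline")) {
    ev <- evaluation[[ref]]
    for (gt in c("visual", "volumetric")) {
      conf <- ev[[paste0("confusion_vs_", gt)]]
      roc <- ev[[paste0("roc_vs_", gt)]]
      d <- ev$delay_vs_volumetric
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, ground_truth = gt, n = conf$n,
        fn_pct = conf$percent[["fn"]], fp_pct = conf$percent[["fp"]],
        tn_pct = conf$percent[["tn"]], tp_pct = conf$percent[["tp"]],
        overall_accuracy_pct = conf$overall_accuracy,
        auc = if (inherits(roc, "roc_result")) roc$auc else NA_real_,
        median_fn_delay_yr = if (gt == "volumetric") d$median_fn_delay else NA_real_,
        median_fp_delay_yr = if (gt == "volumetric") d$median_fp_delay else NA_real_)
    }
  }
  do.call(rbind, rows)
}

# JSON-serializable view of the evaluation report
report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "roc_result"))
      return(x[c("auc", "se_auc", "p_vs_half", "sensitivity", "specificity",
                 "youden", "n")])
    if (inherits(x, "confusion_summary"))
      return(list(counts = as.list(x$counts), percent = as.list(x$percent),
                  n = x$n, overall_accuracy = x$overall_accuracy))
    if (inherits(x, "delay_result"))
      return(x[c("median_fn_delay", "median_fp_delay", "p_value",
                 "n_fn_excluded", "n_fp_excluded", "test_method")])
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  list(evaluation = strip(report$evaluation),
       agreement = report$agreement,
       failures = report$failures,
       n_subjects = length(unique(report$tables$detection_times$subject)))
}

#' @export
print.pipeline_report <- function(x, ...) {
  det <- x$tables$detection_times
  cat(sprintf("Pipeline report: %d subjects (%d growing), %d failures\n",
              nrow(det), sum(det$growing), length(x$failures)))
  for (ref in c("previous", "baseline")) {
    ev <- x$evaluation[[ref]]
    cat(sprintf("  [%s] vs visual: accuracy %.2f%%; vs volumetric: accuracy %.2f%%\n",
                ref, ev$confusion_vs_visual$overall_accuracy,
                ev$confusion_vs_volumetric$overall_accuracy))
    cat(sprintf("  [%s] delay: median FN %.2f yr vs FP %.2f yr\n", ref,
                ev$delay_vs_volumetric$median_fn_delay,
                ev$delay_vs_volumetric$median_fp_delay))
  }
  invisible(x)
}
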