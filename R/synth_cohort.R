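# Synthetic longitudinal cohort generation. Each subject is an ellipsoidal
# main lesion (optionally perturbed by a low-order spherical-harmonic margin
# and accompanied by spherical satellite lesions) rasterized onto an axial
# acquisition grid at every scan time, with known true volumes and a known
# growth change-point.

# Real low-order spherical-harmonic-style direction field, evaluated on unit
# directions (n x 3 matrix). Coefficients fixed per subject; normalized so
# max |P| = 1 over a dense direction sample.
sh_perturbation <- function(coefs) {
  basis <- function(u) {
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    cbind(3 * z^2 - 1, x^2 - y^2, x * y, x * z, y * z,
          x * (5 * z^2 - 1), y * (5 * z^2 - 1))
  }
  th <- seq(0, pi, length.out = 40)
  ph <- seq(0, 2 * pi, length.out = 80)
  grid <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
                rep(cos(th), times = length(ph)))
  scale <- max(abs(drop(basis(grid) %*% coefs)))
  if (scale <= 0) scale <- 1
  function(u) drop(basis(u) %*% coefs) / scale
}

# Voxel-center coordinate arrays (mm) for an acquisition grid.
# Axis 1 = axial stacking (spacing inter_slice_distance), axes 2-3 in-plane.
grid_coordinates <- function(acq) {
  d <- acq$grid_shape
  z <- (seq_len(d[1]) - 1) * acq$inter_slice_distance
  x <- (seq_len(d[2]) - 1) * acq$in_plane_spacing
  y <- (seq_len(d[3]) - 1) * acq$in_plane_spacing
  list(z = z, x = x, y = y,
       center = c(z[1] + diff(range(z)) / 2,
                  x[1] + diff(range(x)) / 2,
                  y[1] + diff(range(y)) / 2))
}

# Rasterize one perturbed ellipsoid: voxel center inside iff its normalized
# ellipsoidal radius rho satisfies rho <= 1 + irregularity * P(direction).
rasterize_lesion <- function(acq, center, semi_axes, irregularity = 0,
                             perturb = NULL) {
  g <- grid_coordinates(acq)
  d <- acq$grid_shape
  Z <- array(rep(g$z, times = d[2] * d[3]), d) - center[1]
  X <- array(rep(rep(g$x, each = d[1]), times = d[3]), d) - center[2]
  Y <- array(rep(g$y, each = d[1] * d[2]), d) - center[3]
  uz <- Z / semi_axes[3]; ux <- X / semi_axes[1]; uy <- Y / semi_axes[2]
  rho <- sqrt(ux^2 + uy^2 + uz^2)
  if (irregularity > 0 && !is.null(perturb)) {
    lim <- array(1, d)
    near <- which(rho > 0 & rho <= 1 + irregularity + 1e-12)
    if (length(near)) {
      u <- cbind(ux[near], uy[near], uz[near]) / rho[near]
      lim[near] <- 1 + irregularity * perturb(u)
    }
    mask <- rho <= lim & rho > 0
    mask[rho == 0] <- TRUE
  } else {
    mask <- rho <= 1
  }
  mask
}

# Cumulative true-volume factor at each scan under a growth model.
volume_factors <- function(spec) {
  n <- length(spec$scan_times)
  k <- seq_len(n)
  switch(spec$growth_model,
         stable = rep(1, n),
         continuous = (1 + spec$growth_rate)^(k - 1),
         change_point = (1 + spec$growth_rate)^pmax(0, k - spec$change_time))
}

#' Generate a synthetic longitudinal tumor cohort
#'
#' Produces, for each trajectory specification, a per-scan series of binary
#' tumor masks ([label_volume]) realizing the subject's growth model on the
#' given acquisition grid, together with the analytic true volumes and the
#' ground-truth change-point. Deterministic given `seed`.
#'
#' True volume accounting: the main lesion contributes `4/3 pi a b c` scaled
#' by the cumulative growth factor (exact for `margin_irregularity = 0`;
#' growth rescales the same shape, so volume *ratios* between scans are exact
#' at any irregularity); each satellite contributes its sphere volume. Under
#' `growth_site = "satellite"` the per-scan factor applies to the satellite
#' volume only (plus `main_growth_rate` on the main lesion); under
#' `"out_of_plane"` the through-plane semi-axis carries the whole factor.
#'
#' @param specs A list of [trajectory_spec] objects (or a single one).
#' @param acq An [acquisition_params] object shared by the cohort.
#' @param seed Integer seed; every random draw (margin perturbation,
#'   satellite placement) derives from it.
#' @param render_intensity If `TRUE`, also render an [intensity_volume] per
#'   scan via [render_intensity()].
#' @param class_means,noise_sd Passed to [render_intensity()] when rendering.
#' @param on_error `"stop"` (default) aborts on the first failing subject
#'   with an error naming it; `"skip"` drops failing subjects (with a
#'   warning) and records their error messages in the result's `"failures"`
#'   attribute, so a large simulated cohort run can isolate bad draws.
#' @return A list of subject records, each with elements `subject`, `spec`,
#'   `scans` (list of `label_volume`, plus `intensity` when rendered),
#'   `true_volumes_cm3`, `true_change_index` (last pre-growth scan index or
#'   `NA`) and `true_onset_time` (time of the first grown scan or `NA`).
#' @export
generate_cohort <- function(specs, acq, seed,
                            render_intensity = FALSE,
                            class_means = c(background = 5, gray_matter = 60,
                                            white_matter = 40, tumor = 100),
                            noise_sd = 5,
                            on_error = c("stop", "skip")) {
  if (inherits(specs, "trajectory_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0, inherits(acq, "acq_params"))
  lapply(specs, function(s) stopifnot(inherits(s, "trajectory_spec")))
  on_error <- match.arg(on_error)
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max, length(specs))
  out <- vector("list", length(specs))
  failures <- character(0)
  for (i in seq_along(specs)) {
    id <- sprintf("S%03d", i)
    res <- tryCatch(
      generate_subject(id, specs[[i]], acq, subject_seeds[i],
                       render_intensity, class_means, noise_sd),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(res)
      warning("skipping subject ", id, ": ", conditionMessage(res))
      failures[[id]] <- conditionMessage(res)
    } else {
      out[[i]] <- res
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("every subject failed; first error: ", failures[[1]])
  structure(out, failures = failures)
}

generate_subject <- function(id, spec, acq, seed, render, class_means, noise_sd) {
  set.seed(seed %% .Machine$integer.max)
  if (any(spec$baseline_radii <= acq$in_plane_spacing))
    stop(sprintf("subject %s: degenerate radii (<= in-plane spacing)", id))
  g <- grid_coordinates(acq)
  perturb <- if (spec$margin_irregularity > 0)
    sh_perturbation(stats::rnorm(7)) else NULL

  factors <- volume_factors(spec)
  n_scans <- length(spec$scan_times)

  # satellite placement: centers >= 5 mm from the main lesion surface at its
  # largest extent, so components can never merge
  max_factor <- max(factors)
  max_main_grown <- switch(spec$growth_model,
                           stable = 0,
                           continuous = n_scans - 1,
                           change_point = n_scans - spec$change_time)
  sat <- NULL
  if (spec$satellite_count > 0L) {
    sat_r_max <- spec$satellite_radius *
      (if (spec$growth_site == "satellite") max_factor^(1 / 3) else 1)
    main_max <- spec$baseline_radii *
      (1 + spec$margin_irregularity) *
      switch(spec$growth_site,
             isotropic = max_factor^(1 / 3),
             out_of_plane = c(1, 1, max_factor),
             satellite = (1 + spec$main_growth_rate)^(max_main_grown / 3))
    # clearance must survive voxelization: 5 mm plus one grid step, checked
    # against a dense sample of the (inflated) main surface rather than the
    # ray distance, which underestimates for oblique directions
    gap_mm <- 5 + max(acq$inter_slice_distance, acq$in_plane_spacing)
    th <- seq(0.05, pi - 0.05, length.out = 40)
    ph <- seq(0, 2 * pi, length.out = 60)
    dirs <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
                  rep(cos(th), times = length(ph)))
    surf_pts <- sweep(dirs, 2, main_max, `*`)
    centers <- matrix(0, spec$satellite_count, 3)
    for (s in seq_len(spec$satellite_count)) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        surf <- 1 / sqrt(sum((u / main_max)^2))
        # 3 mm slack above the required clearance so the numeric check can
        # pass despite oblique-direction deficits and surface sampling
        cand <- u * (surf + gap_mm + sat_r_max + 3)
        clear <- sqrt(min(colSums((t(surf_pts) - cand)^2))) - sat_r_max
        ok_main <- clear >= gap_mm
        ok_sib <- s == 1L || all(sqrt(colSums((t(centers[seq_len(s - 1L), ,
                                                         drop = FALSE]) - cand)^2)) >=
                                   2 * sat_r_max + gap_mm)
        if (ok_main && ok_sib) { placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("subject %s: could not place disjoint satellites", id))
      centers[s, ] <- cand
    }
    sat <- list(centers = centers, radius = spec$satellite_radius)
  }

  main_vol0 <- 4 / 3 * pi * prod(spec$baseline_radii) / 1000  # cm^3
  sat_vol0 <- if (is.null(sat)) 0 else
    spec$satellite_count * 4 / 3 * pi * spec$satellite_radius^3 / 1000

  scans <- vector("list", n_scans)
  true_vol <- numeric(n_scans)
  for (k in seq_len(n_scans)) {
    f <- factors[k]
    axes <- spec$baseline_radii
    sat_scale <- 1
    if (spec$growth_site == "isotropic") {
      axes <- axes * f^(1 / 3)
      sat_scale <- f^(1 / 3)
      tv <- main_vol0 * f + sat_vol0 * f
    } else if (spec$growth_site == "out_of_plane") {
      axes[3] <- axes[3] * f
      tv <- main_vol0 * f + sat_vol0
    } else { # satellite growth, optional slow isotropic main growth after onset
      grown <- switch(spec$growth_model,
                      stable = 0,
                      continuous = k - 1,
                      change_point = max(0, k - spec$change_time))
      fm <- (1 + spec$main_growth_rate)^grown
      axes <- axes * fm^(1 / 3)
      sat_scale <- f^(1 / 3)
      tv <- main_vol0 * fm + sat_vol0 * f
    }
    center <- c(g$center[1], g$center[2], g$center[3]) # (z, x, y) mm
    mask <- rasterize_lesion(acq, center, axes,
                             spec$margin_irregularity, perturb)
    if (!is.null(sat)) {
      for (s in seq_len(nrow(sat$centers))) {
        cs <- center + sat$centers[s, c(3, 1, 2)] # (z, x, y) offset
        mask <- mask | rasterize_lesion(acq, cs, rep(sat$radius * sat_scale, 3))
      }
    }
    if (sum(mask) == 0L)
      stop(sprintf("subject %s: lesion vanished at scan %d (grid too coarse)", id, k))
    if (mask_touches_border(mask) || border_clearance(mask) < 2L)
      stop(sprintf("subject %s: tumor exceeds the grid at scan %d", id, k))
    if (!is.null(sat)) {
      n_comp <- max(label_components(mask))
      if (n_comp != 1L + spec$satellite_count)
        stop(sprintf("subject %s: satellite merged with main lesion at scan %d", id, k))
    }
    lv <- label_volume(mask, acq, spec$scan_times[k])
    if (render) {
      lv_int <- render_intensity(lv, class_means, noise_sd,
                                 seed = (seed + k) %% .Machine$integer.max)
      scans[[k]] <- list(label = lv, intensity = lv_int)
    } else {
      scans[[k]] <- list(label = lv)
    }
    true_vol[k] <- tv
  }
  list(subject = id, spec = spec, scans = scans,
       true_volumes_cm3 = true_vol,
       true_change_index = if (spec$growth_model == "change_point")
         spec$change_time else NA_integer_,
       true_onset_time = if (spec$growth_model == "change_point")
         spec$scan_times[spec$change_time + 1L] else NA_real_)
}

border_clearance <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  min(c(idx - 1L, sweep(-idx, 2, d, `+`)))
}

#' Render a synthetic intensity volume around a tumor mask
#'
#' Builds a piecewise-constant head phantom (background, a brain ellipsoid
#' whose outer rim is gray matter and interior is white matter, and the tumor
#' mask) and adds i.i.d. Gaussian noise. The tumor class mean must exceed the
#' gray-matter mean.
#'
#' @param label A [label_volume]; its geometry defines the grid.
#' @param class_means Named vector of class mean intensities (`background`,
#'   `gray_matter`, `white_matter`, `tumor`), arbitrary units.
#' @param noise_sd Gaussian noise SD (>= 0), same units.
#' @param seed Integer seed (noise is deterministic given it).
#' @param rim_voxels Thickness of the gray-matter rim, in voxels.
#' @return An [intensity_volume] carrying `class_means` and `noise_sd`.
#' @export
render_intensity <- function(label, class_means = c(background = 5,
                                                    gray_matter = 60,
                                                    white_matter = 40,
                                                    tumor = 100),
                             noise_sd = 5, seed = 1L, rim_voxels = 3L) {
  stopifnot(inherits(label, "label_volume"), noise_sd >= 0)
  if (class_means[["tumor"]] <= class_means[["gray_matter"]])
    stop("tumor class mean must exceed gray_matter mean")
  acq <- label$geometry
  d <- acq$grid_shape
  g <- grid_coordinates(acq)
  brain_axes <- c(0.42 * diff(range(g$x)), 0.42 * diff(range(g$y)),
                  0.46 * diff(range(g$z)))
  brain <- rasterize_lesion(acq, g$center, brain_axes)
  interior <- erode_mask(brain, rim_voxels)
  values <- array(class_means[["background"]], d)
  values[brain] <- class_means[["gray_matter"]]
  values[interior] <- class_means[["white_matter"]]
  values[label$mask] <- class_means[["tumor"]]
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    values <- values + array(stats::rnorm(prod(d), 0, noise_sd), d)
  }
  intensity_volume(values, acq, class_means, noise_sd)
}
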