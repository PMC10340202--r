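#' Acquisition geometry for an axial scan stack
#'
#' Describes how a 3D mask or intensity volume is sampled: isotropic in-plane
#' voxel spacing, slice thickness, and the center-to-center inter-slice
#' distance (thickness + gap) used to convert summed slice areas to volume.
#'
#' @param in_plane_spacing In-plane voxel size in mm (isotropic within a slice).
#' @param slice_thickness Slice thickness in mm.
#' @param inter_slice_distance Center-to-center axial spacing in mm; must be at
#'   least `slice_thickness` (the difference is the inter-slice gap).
#' @param grid_shape Integer vector `c(n_slices, n_x, n_y)`; the axial slice
#'   axis is the first (stacking) dimension.
#'
#' @return An object of class `acq_params`.
#' @seealso [sample_acquisition_params()] for drawing parameters from the
#'   clinical FLAIR ranges this package emulates.
#' @export
acquisition_params <- function(in_plane_spacing, slice_thickness,
                               inter_slice_distance, grid_shape) {
  stopifnot(is.numeric(in_plane_spacing), length(in_plane_spacing) == 1L,
            is.numeric(slice_thickness), length(slice_thickness) == 1L,
            is.numeric(inter_slice_distance), length(inter_slice_distance) == 1L)
  if (in_plane_spacing <= 0 || slice_thickness <= 0 || inter_slice_distance <= 0)
    stop("all spacings must be positive")
  if (inter_slice_distance < slice_thickness - 1e-9)
    stop("inter_slice_distance (center-to-center) cannot be smaller than slice_thickness")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 3L))
    stop("grid_shape must be three integers >= 3 (n_slices, n_x, n_y)")
  structure(list(in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness,
                 inter_slice_distance = inter_slice_distance,
                 grid_shape = grid_shape),
            class = "acq_params")
}

#' Sample acquisition parameters from the clinical FLAIR ranges
#'
#' Draws slice thickness in \[1, 6\] mm and an inter-slice gap in \[0.6, 7.5\]
#' mm, the ranges reported for routine 2D FLAIR acquisitions of lower-grade
#' gliomas; the defaults of [default_acquisition()] sit at the reported medians
#' (5 mm thickness, 6.5 mm center-to-center distance).
#'
#' @param grid_shape Grid dimensions, `c(n_slices, n_x, n_y)`.
#' @param in_plane_spacing In-plane spacing in mm.
#' @param seed Optional integer seed for reproducibility.
#' @return An `acq_params` object.
#' @export
sample_acquisition_params <- function(grid_shape = c(24L, 96L, 96L),
                                      in_plane_spacing = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  thick <- stats::runif(1, 1, 6)
  gap <- stats::runif(1, 0.6, 7.5)
  acquisition_params(in_plane_spacing, thick, thick + gap, grid_shape)
}

#' @rdname sample_acquisition_params
#' @export
default_acquisition <- function(grid_shape = c(24L, 96L, 96L),
                                in_plane_spacing = 1) {
  acquisition_params(in_plane_spacing, 5, 6.5, grid_shape)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("Acquisition: %.3g mm in-plane, %.3g mm slices, %.3g mm apart; grid %s\n",
              x$in_plane_spacing, x$slice_thickness, x$inter_slice_distance,
              paste(x$grid_shape, collapse = " x ")))
  invisible(x)
}

#' Binary tumor mask for one scan
#'
#' A 3D binary mask stacked along axial slices (first array dimension), with
#' its acquisition geometry and scan time. The mask must not touch the grid
#' border, so that boundary-based diameter measurement is well defined.
#'
#' @param mask 3D logical or 0/1 array, `dim = geometry$grid_shape`.
#' @param geometry An `acq_params` object.
#' @param scan_time Scan time in years (may be `NA` for a standalone volume).
#' @param check If `TRUE`, verify dimensions and border clearance.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(mask, geometry, scan_time = NA_real_, check = TRUE) {
  stopifnot(inherits(geometry, "acq_params"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (check) {
    if (!identical(dim(mask), NULL) && !all(dim(mask) == geometry$grid_shape))
      stop("mask dimensions do not match geometry$grid_shape")
    if (mask_touches_border(mask))
      stop("mask touches the grid border; enlarge the grid")
  }
  structure(list(mask = mask, geometry = geometry, scan_time = scan_time),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume: %d foreground voxels, t = %s yr\n",
              sum(x$mask), format(x$scan_time)))
  print(x$geometry)
  invisible(x)
}

#' Synthetic intensity volume
#'
#' A real-valued 3D image with per-class mean intensities; the tumor class
#' mean must exceed the gray-matter mean so that gray-level thresholding of
#' intensity-ranked segments is well posed.
#'
#' @param values 3D numeric array.
#' @param geometry An `acq_params` object.
#' @param class_means Named numeric vector with at least `background`,
#'   `gray_matter`, `white_matter` and `tumor` entries (arbitrary units).
#' @param noise_sd Gaussian noise SD, same units as `class_means`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, geometry, class_means, noise_sd) {
  stopifnot(inherits(geometry, "acq_params"), is.numeric(noise_sd), noise_sd >= 0)
  req <- c("background", "gray_matter", "white_matter", "tumor")
  if (!all(req %in% names(class_means)))
    stop("class_means must name: ", paste(req, collapse = ", "))
  if (class_means[["tumor"]] <= class_means[["gray_matter"]])
    stop("tumor class mean must exceed gray_matter mean")
  if (any(!is.finite(values))) stop("intensity values must be finite")
  structure(list(values = values, geometry = geometry,
                 class_means = class_means, noise_sd = noise_sd),
            class = "intensity_volume")
}

#' Growth trajectory specification for one synthetic subject
#'
#' Defines a subject's true tumor time course: an ellipsoidal main lesion
#' (optionally with an irregular, infiltrative-looking margin and satellite
#' lesions) whose true volume is constant (`stable`), grows by a fixed
#' fraction every scan (`continuous`), or switches abruptly from stable to
#' growing after scan `change_time` (`change_point`).
#'
#' `growth_site` controls where the added volume is placed, which is what
#' makes growth visible or occult to a single axial cross-section:
#' `isotropic` scales all semi-axes, `out_of_plane` stretches only the
#' through-plane axis (the measured equatorial cross-section barely changes),
#' and `satellite` grows only the satellite lesions (invisible to a
#' largest-component bidimensional measurement).
#'
#' @param baseline_radii Ellipsoid semi-axes in mm, `c(in-plane a, in-plane b,
#'   through-plane c)`.
#' @param growth_model One of `"stable"`, `"continuous"`, `"change_point"`.
#' @param change_time Scan index of the last pre-growth scan (growth applies
#'   from scan `change_time + 1`); required iff `growth_model = "change_point"`.
#' @param growth_rate Fractional true-volume increase per scan after onset.
#' @param satellite_count Number of satellite lesions (>= 0).
#' @param satellite_radius Satellite sphere radius in mm.
#' @param margin_irregularity Amplitude (>= 0) of the low-order
#'   spherical-harmonic margin perturbation; 0 gives an exact ellipsoid.
#' @param scan_times Strictly increasing scan times in years; at least 4 scans
#'   (the series-analysis inclusion rule).
#' @param growth_site One of `"isotropic"`, `"out_of_plane"`, `"satellite"`.
#' @param main_growth_rate For `growth_site = "satellite"`: optional slow
#'   isotropic growth rate of the main lesion (default 0), applied on the
#'   same schedule as `growth_rate` (i.e. after the change point), letting
#'   the main mass creep while satellites account for most added volume.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(baseline_radii,
                            growth_model = c("stable", "continuous", "change_point"),
                            change_time = NULL,
                            growth_rate = 0,
                            satellite_count = 0L,
                            satellite_radius = 4,
                            margin_irregularity = 0,
                            scan_times = seq(0, by = 0.5, length.out = 6L),
                            growth_site = c("isotropic", "out_of_plane", "satellite"),
                            main_growth_rate = 0) {
  growth_model <- match.arg(growth_model)
  growth_site <- match.arg(growth_site)
  stopifnot(length(baseline_radii) == 3L, all(baseline_radii > 0),
            growth_rate >= 0, main_growth_rate >= 0,
            satellite_count >= 0, satellite_radius > 0,
            margin_irregularity >= 0)
  if (length(scan_times) < 4L || any(diff(scan_times) <= 0))
    stop("scan_times must be >= 4 strictly increasing times")
  if (growth_model == "change_point") {
    if (is.null(change_time))
      stop("change_time is required for growth_model = 'change_point'")
    change_time <- as.integer(change_time)
    if (change_time < 1L || change_time >= length(scan_times))
      stop("change_time must index a scan before the last one")
  } else if (!is.null(change_time)) {
    stop("change_time is only meaningful for growth_model = 'change_point'")
  }
  if (growth_site == "satellite" && satellite_count < 1L)
    stop("growth_site = 'satellite' requires satellite_count >= 1")
  structure(list(baseline_radii = as.numeric(baseline_radii),
                 growth_model = growth_model,
                 change_time = change_time,
                 growth_rate = growth_rate,
                 satellite_count = as.integer(satellite_count),
                 satellite_radius = satellite_radius,
                 margin_irregularity = margin_irregularity,
                 scan_times = as.numeric(scan_times),
                 growth_site = growth_site,
                 main_growth_rate = main_growth_rate),
            class = "trajectory_spec")
}
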