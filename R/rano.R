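# RANO bidirectional measurement on axial mask stacks.
#
# The measured quantity is the product of the longest in-plane diameter (d1)
# and the longest diameter perpendicular to it (d2) on the axial slice with
# the largest tumor cross-section, in cm^2. Only the largest connected
# component of a slice is measured: a bidimensional single-lesion
# measurement is blind to satellite components by construction.

#' A bidimensional (RANO) measurement
#'
#' @param slice_index Axial slice on which the diameters were measured.
#' @param d1 Longest in-plane diameter, cm.
#' @param d2 Longest diameter perpendicular (within tolerance) to `d1`, cm.
#'   Note `d2 <= d1` is not required in general: `d2` is the longest
#'   perpendicular chord, not the second-longest overall.
#' @param endpoints_d1,endpoints_d2 2x2 matrices of segment endpoints in mm
#'   (rows = endpoints, columns = in-plane axes), or `NULL`.
#' @param cross_section_area Foreground area of the measured slice, cm^2.
#' @param degenerate `TRUE` when the component was too small to span a
#'   perpendicular chord (both diameters fall back to the voxel caliper
#'   width).
#' @return An object of class `rano_measurement`; `product` is always
#'   exactly `d1 * d2`.
#' @export
rano_measurement <- function(slice_index, d1, d2, endpoints_d1 = NULL,
                             endpoints_d2 = NULL, cross_section_area = NA_real_,
                             degenerate = FALSE) {
  stopifnot(d1 >= 0, d2 >= 0)
  structure(list(slice_index = as.integer(slice_index),
                 d1 = d1, d2 = d2, product = d1 * d2,
                 endpoints_d1 = endpoints_d1, endpoints_d2 = endpoints_d2,
                 cross_section_area = cross_section_area,
                 degenerate = isTRUE(degenerate)),
            class = "rano_measurement")
}

#' @export
print.rano_measurement <- function(x, ...) {
  cat(sprintf("RANO measurement: slice %d, d1 = %.2f cm, d2 = %.2f cm, product = %.2f cm^2\n",
              x$slice_index, x$d1, x$d2, x$product))
  invisible(x)
}

#' Find the axial slice with the largest tumor cross-section
#'
#' @param label A [label_volume] with a non-empty mask.
#' @return A list with `slice_index` (ties broken by the lowest index) and
#'   `area_cm2` (foreground voxel count times in-plane voxel area).
#' @export
largest_cross_section <- function(label) {
  stopifnot(inherits(label, "label_volume"))
  counts <- apply(label$mask, 1, sum)
  if (sum(counts) == 0L)
    stop("no tumor: the mask is empty", call. = FALSE)
  idx <- which.max(counts)  # which.max returns the first (lowest) maximum
  area <- counts[idx] * label$geometry$in_plane_spacing^2 / 100
  list(slice_index = as.integer(idx), area_cm2 = area)
}

# Boundary voxels (4-connectivity) of a 2D component, as an n x 2 matrix of
# mm coordinates of voxel centers, ordered by (row, col).
boundary_points <- function(slice_mask, spacing) {
  interior <- erode_mask(slice_mask, 1L)
  bd <- which(slice_mask & !interior, arr.ind = TRUE)
  bd <- bd[order(bd[, 1], bd[, 2]), , drop = FALSE]
  (bd - 1) * spacing
}

# Deterministic representative of a point pair: endpoints ordered so the
# lexicographically smaller comes first; among equal-length candidates the
# lexicographically smallest ordered pair wins.
order_pair <- function(p, q) {
  if (p[1] < q[1] || (p[1] == q[1] && p[2] <= q[2])) rbind(p, q) else rbind(q, p)
}

pick_pair <- function(pts, ii, jj, dist) {
  best <- max(dist)
  cand <- which(dist >= best - 1e-9)
  reps <- lapply(cand, function(m) order_pair(pts[ii[m], ], pts[jj[m], ]))
  keys <- vapply(reps, function(r) sprintf("%.6f|%.6f|%.6f|%.6f",
                                           r[1, 1], r[1, 2], r[2, 1], r[2, 2]),
                 character(1))
  reps[[order(keys)[1]]]
}

#' Longest diameter and longest perpendicular diameter of a slice component
#'
#' Measures the largest connected component (4-connectivity) of a 2D binary
#' slice. `d1` is the maximum Euclidean distance between boundary-voxel
#' centers, found by an exhaustive search over convex-hull vertices
#' (equivalent to searching all boundary pairs). `d2` is the maximum distance
#' between boundary-point pairs whose direction lies within
#' `perp_tol_deg` degrees of perpendicular to `d1`. Ties are broken by the
#' lexicographically smallest endpoint pair, making the result deterministic.
#'
#' @param slice_mask 2D binary matrix (non-empty).
#' @param in_plane_spacing In-plane voxel size, mm.
#' @param perp_tol_deg Perpendicularity tolerance in degrees (default 5).
#' @return A list: `d1_cm`, `d2_cm`, `endpoints_d1`, `endpoints_d2` (mm
#'   coordinates), `degenerate`. A single-voxel (or perpendicular-chord-free)
#'   component yields the voxel caliper width for the missing diameter and
#'   `degenerate = TRUE`.
#' @export
bidiameter <- function(slice_mask, in_plane_spacing, perp_tol_deg = 5) {
  stopifnot(is.matrix(slice_mask) || length(dim(slice_mask)) == 2L,
            in_plane_spacing > 0)
  slice_mask <- matrix(as.logical(slice_mask), nrow = dim(slice_mask)[1])
  if (!any(slice_mask)) stop("empty slice mask")
  comp <- largest_component(slice_mask)
  pts <- boundary_points(comp, in_plane_spacing)
  n <- nrow(pts)
  if (n == 1L) {
    return(list(d1_cm = in_plane_spacing / 10, d2_cm = in_plane_spacing / 10,
                endpoints_d1 = rbind(pts[1, ], pts[1, ]),
                endpoints_d2 = rbind(pts[1, ], pts[1, ]),
                degenerate = TRUE))
  }
  # d1 over convex hull vertices (max pairwise distance is attained there)
  hull <- unique(grDevices::chull(pts[, 1], pts[, 2]))
  hp <- pts[hull, , drop = FALSE]
  hi <- rep(seq_len(nrow(hp)), times = nrow(hp))
  hj <- rep(seq_len(nrow(hp)), each = nrow(hp))
  keep <- hi < hj
  hi <- hi[keep]; hj <- hj[keep]
  hd <- sqrt((hp[hi, 1] - hp[hj, 1])^2 + (hp[hi, 2] - hp[hj, 2])^2)
  ep1 <- pick_pair(hp, hi, hj, hd)
  d1_mm <- max(hd)
  u <- (ep1[2, ] - ep1[1, ]) / d1_mm

  # d2 over all boundary pairs within the angular tolerance, chunked to keep
  # the pair expansion memory-bounded on large boundaries
  sin_tol <- sin(perp_tol_deg * pi / 180) + 1e-12
  best_d <- -Inf; best_ii <- integer(0); best_jj <- integer(0); best_dist <- numeric(0)
  chunk <- max(1L, floor(4e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    ii <- rep(rows, each = n)
    jj <- rep(seq_len(n), times = length(rows))
    keep <- ii < jj
    ii <- ii[keep]; jj <- jj[keep]
    if (!length(ii)) next
    dx <- pts[jj, 1] - pts[ii, 1]
    dy <- pts[jj, 2] - pts[ii, 2]
    len <- sqrt(dx^2 + dy^2)
    ok <- len > 0 & abs(dx * u[1] + dy * u[2]) / len <= sin_tol
    if (!any(ok)) next
    ii <- ii[ok]; jj <- jj[ok]; len <- len[ok]
    mx <- max(len)
    if (mx > best_d + 1e-9) {
      sel <- len >= mx - 1e-9
      best_d <- mx; best_ii <- ii[sel]; best_jj <- jj[sel]; best_dist <- len[sel]
    } else if (mx >= best_d - 1e-9) {
      sel <- len >= best_d - 1e-9
      best_ii <- c(best_ii, ii[sel]); best_jj <- c(best_jj, jj[sel])
      best_dist <- c(best_dist, len[sel])
      best_d <- max(best_d, mx)
    }
  }
  if (!is.finite(best_d)) {
    # no perpendicular chord exists (e.g., collinear boundary): fall back to
    # the voxel caliper width
    return(list(d1_cm = d1_mm / 10, d2_cm = in_plane_spacing / 10,
                endpoints_d1 = ep1, endpoints_d2 = NULL, degenerate = TRUE))
  }
  ep2 <- pick_pair(pts, best_ii, best_jj, best_dist)
  list(d1_cm = d1_mm / 10, d2_cm = best_d / 10,
       endpoints_d1 = ep1, endpoints_d2 = ep2, degenerate = FALSE)
}

#' Measure a 3D mask with the RANO rule
#'
#' Selects the axial slice with the largest cross-section
#' ([largest_cross_section]) and computes the bidimensional product on it
#' ([bidiameter]).
#'
#' @param label A [label_volume].
#' @param perp_tol_deg Perpendicularity tolerance passed to [bidiameter].
#' @return A [rano_measurement].
#' @export
rano_measure <- function(label, perp_tol_deg = 5) {
  sel <- largest_cross_section(label)
  bd <- bidiameter(label$mask[sel$slice_index, , ],
                   label$geometry$in_plane_spacing, perp_tol_deg)
  rano_measurement(sel$slice_index, bd$d1_cm, bd$d2_cm,
                   bd$endpoints_d1, bd$endpoints_d2,
                   cross_section_area = sel$area_cm2,
                   degenerate = bd$degenerate)
}

#' Classify growth of a bidimensional product against a reference
#'
#' Progression for lower-grade gliomas is a >= 25% increase of the diameter
#' product relative to the reference measurement (previous or baseline scan).
#' The boundary case is inclusive by default (`>= 25%` counts as growth) and
#' configurable.
#'
#' @param current,reference [rano_measurement] objects or bare products in
#'   cm^2; the reference product must be positive.
#' @param threshold Fractional growth threshold (default 0.25).
#' @param inclusive If `TRUE` (default) a change exactly at the threshold is
#'   called growth.
#' @return A list: `percent_change` (100 x fractional change) and `call`
#'   (1 = growth, 0 = no growth).
#' @export
classify_growth <- function(current, reference, threshold = 0.25,
                            inclusive = TRUE) {
  p_cur <- if (inherits(current, "rano_measurement")) current$product else current
  p_ref <- if (inherits(reference, "rano_measurement")) reference$product else reference
  stopifnot(is.numeric(p_cur), is.numeric(p_ref))
  if (p_ref <= 0)
    stop("reference product must be positive (empty reference tumor must be handled upstream)")
  pc <- 100 * (p_cur - p_ref) / p_ref
  call <- if (inclusive) pc >= 100 * threshold else pc > 100 * threshold
  list(percent_change = pc, call = as.integer(call))
}

#' Multi-operator consensus growth call
#'
#' @param calls Binary vector of per-operator growth calls (non-empty).
#' @param k Number of concordant growth calls required (default 2, the
#'   two-of-three clinician rule).
#' @return 1 if at least `k` of the calls are 1, else 0.
#' @export
consensus_call <- function(calls, k = 2L) {
  if (length(calls) == 0L) stop("empty call set")
  stopifnot(all(calls %in% c(0, 1)), k >= 1, k <= length(calls))
  as.integer(sum(calls) >= k)
}
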