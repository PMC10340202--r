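# Intensity-based segmentation sketch: a non-negative matrix factorization
# of a voxel x intensity-feature representation into k = 8 components,
# ranked by their characteristic intensities; the tumor mask is the union of
# components brighter than the gray-matter level, regularized
# morphologically.

# Multiplicative-update NMF (Frobenius objective). Deterministic given the
# seed and the fixed iteration cap; the objective is non-increasing.
#
# Initialization is anchored: component j starts as a Gaussian bump over the
# feature axis at `anchors[j]` (feature-index units), with W seeded by each
# row's similarity to that bump plus seeded jitter. Anchoring at the image's
# intensity modes keeps components aligned with tissue classes, so minority
# classes (the tumor is typically a few percent of the voxels) are not
# absorbed by the dominant background during the updates.
nmf_factorize <- function(V, k, seed = 1L, n_iter = 200L, eps = 1e-9,
                          anchors = NULL) {
  stopifnot(all(V >= 0), k >= 2L, n_iter >= 1L)
  set.seed(as.integer(seed))
  n <- nrow(V); m <- ncol(V)
  if (is.null(anchors)) anchors <- seq(1, m, length.out = k)
  stopifnot(length(anchors) == k)
  H <- t(vapply(anchors, function(a) exp(-0.5 * ((seq_len(m) - a) / (m / k))^2),
                numeric(m)))
  H <- H + matrix(stats::runif(k * m, 0, 0.01), k, m)
  W <- V %*% t(H) + matrix(stats::runif(n * k, 0, 0.01), n, k)
  err <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err[it] <- sqrt(sum((V - W %*% H)^2))
  }
  list(W = W, H = H, error = err)
}

# Component anchor positions on the feature axis: one anchor per intensity
# mode of a kernel density estimate of the image (up to k modes, by
# decreasing height, greedily enforcing a minimum separation of one feature
# bin so noise wiggle inside a class cannot spawn several anchors),
# remaining anchors placed at the feature positions farthest from any
# existing anchor so unused components start spread out and can die off.
mode_anchors <- function(x, centers, k) {
  if (stats::sd(x) == 0) {
    return(seq(1, length(centers), length.out = k))
  }
  den <- stats::density(x, n = 512)
  y <- den$y
  np <- length(y)
  is_peak <- y >= c(-Inf, y[-np]) & y >= c(y[-1], -Inf)
  cand <- den$x[is_peak][order(y[is_peak], decreasing = TRUE)]
  w <- diff(centers[1:2])
  modes <- numeric(0)
  for (v in cand) {
    if (length(modes) == k) break
    if (all(abs(v - modes) >= w)) modes <- c(modes, v)
  }
  to_pos <- function(v) 1 + (v - centers[1]) / w
  anchors <- sort(to_pos(modes))
  m <- length(centers)
  while (length(anchors) < k) {
    grid <- seq(1, m, length.out = 8L * k)
    gap <- vapply(grid, function(p) min(abs(p - anchors)), numeric(1))
    anchors <- sort(c(anchors, grid[which.max(gap)]))
  }
  anchors
}

# Gaussian soft-binning features: voxel i -> exp(-((x_i - c_b)/w)^2 / 2)
# over n_bins equally spaced intensity centers. Voxels of similar intensity
# share features, so NMF components align with intensity levels.
intensity_features <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  centers <- seq(rng[1], rng[2], length.out = n_bins)
  w <- diff(centers[1:2])
  F <- exp(-0.5 * ((outer(x, centers, `-`)) / w)^2)
  list(features = F, centers = centers)
}

#' Decompose an intensity volume into intensity-ranked regions
#'
#' Factorizes the voxel x intensity-feature matrix of the image into `k`
#' non-negative components and assigns every voxel to its maximal-loading
#' component. Each segment is summarized by its characteristic intensity
#' (the intensity-bin center at the peak of its basis profile) and the
#' segments are ranked by that intensity in descending order.
#'
#' @param image An [intensity_volume] (finite values; shifted internally if
#'   needed so the feature matrix stays non-negative, which it is by
#'   construction).
#' @param k Number of segments (default 8; must be >= 2).
#' @param n_bins Number of intensity feature bins (default 8; bins about as wide as a tissue class, so noise cannot split a class across components).
#' @param seed Integer seed for the factorization initialization.
#' @param n_iter Multiplicative-update iterations (default 200).
#' @return An object of class `region_decomposition`: `assignment` (integer
#'   array over the grid), `segment_intensity` (characteristic intensity per
#'   segment, `NA` for empty segments), `rank_order` (segment indices by
#'   descending intensity), `k`, `geometry`, and `degenerate` (`TRUE` when
#'   fewer than 2 segments are populated, e.g. for a constant image).
#' @export
decompose_regions <- function(image, k = 8L, n_bins = 8L, seed = 1L,
                              n_iter = 200L) {
  stopifnot(inherits(image, "intensity_volume"))
  if (k < 2L) stop("k must be >= 2")
  x <- as.vector(image$values)
  if (any(!is.finite(x))) stop("non-finite voxels in intensity volume")
  if (stats::sd(x) == 0) {
    # a constant image has one intensity level: a single populated segment,
    # flagged degenerate (the jittered factorization would otherwise scatter
    # argmax ties across components)
    warning("degenerate decomposition: fewer than 2 populated segments (constant image?)")
    seg_int <- c(x[1], rep(NA_real_, k - 1L))
    return(structure(list(assignment = array(1L, dim = dim(image$values)),
                          segment_intensity = seg_int,
                          bin_width = 1,
                          rank_order = order(seg_int, decreasing = TRUE,
                                             na.last = TRUE),
                          k = as.integer(k),
                          geometry = image$geometry,
                          degenerate = TRUE,
                          fit_error = numeric(0)),
                     class = "region_decomposition"))
  }
  feat <- intensity_features(x, n_bins)
  fit <- nmf_factorize(feat$features, k, seed = seed, n_iter = n_iter,
                       anchors = mode_anchors(x, feat$centers, k))
  assignment <- max.col(fit$W, ties.method = "first")
  seg_int <- rep(NA_real_, k)
  populated <- sort(unique(assignment))
  for (j in populated) seg_int[j] <- feat$centers[which.max(fit$H[j, ])]
  degenerate <- length(populated) < 2L
  if (degenerate)
    warning("degenerate decomposition: fewer than 2 populated segments (constant image?)")
  structure(list(assignment = array(assignment, dim = dim(image$values)),
                 segment_intensity = seg_int,
                 bin_width = diff(feat$centers[1:2]),
                 rank_order = order(seg_int, decreasing = TRUE, na.last = TRUE),
                 k = as.integer(k),
                 geometry = image$geometry,
                 degenerate = degenerate,
                 fit_error = fit$error),
            class = "region_decomposition")
}

#' @export
print.region_decomposition <- function(x, ...) {
  cat(sprintf("Region decomposition: %d segments; intensities %s\n", x$k,
              paste(signif(x$segment_intensity[x$rank_order], 3), collapse = ", ")))
  invisible(x)
}

#' Extract a tumor mask from a region decomposition
#'
#' Takes the union of segments whose characteristic intensity exceeds the
#' gray-matter level, then regularizes the boundary: a morphological opening
#' (which removes the thin scatter of noise-tail voxels that fall into
#' above-threshold intensity bands), a closing (which fills interior gaps),
#' and retention of the largest connected component plus any satellite
#' components of at least `min_component` voxels. The regularization step
#' stands in for a level-set refinement and is isolated here.
#'
#' @param decomp A `region_decomposition` from [decompose_regions()].
#' @param gray_level Gray-matter intensity level; segments strictly brighter
#'   are kept. Supply the known phantom level or estimate it with
#'   [estimate_gray_level()].
#' @param margin Guard added to `gray_level` before comparison; defaults to
#'   half the intensity-bin width of the decomposition, absorbing the bin
#'   quantization of the characteristic intensities (a segment representing
#'   gray matter itself may otherwise quantize to just above the level).
#' @param opening_iterations Morphological opening iterations (default 1;
#'   use 0 to skip, e.g. on noiseless images).
#' @param closing_iterations Morphological closing iterations (default 1).
#' @param min_component Minimum satellite component size in voxels
#'   (default 10).
#' @param scan_time Scan time attached to the returned volume.
#' @return A [label_volume]; empty (with a warning) when no segment exceeds
#'   `gray_level`.
#' @export
extract_tumor_mask <- function(decomp, gray_level, margin = NULL,
                               opening_iterations = 1L,
                               closing_iterations = 1L,
                               min_component = 10L, scan_time = NA_real_) {
  stopifnot(inherits(decomp, "region_decomposition"), is.finite(gray_level))
  if (is.null(margin)) margin <- decomp$bin_width / 2
  keep <- which(!is.na(decomp$segment_intensity) &
                  decomp$segment_intensity > gray_level + margin)
  if (length(keep) == 0L) {
    warning("no segment brighter than gray_level: returning an empty mask")
    return(label_volume(array(FALSE, dim(decomp$assignment)), decomp$geometry,
                        scan_time, check = FALSE))
  }
  mask <- array(decomp$assignment %in% keep, dim(decomp$assignment))
  if (opening_iterations > 0L)
    mask <- dilate_mask(erode_mask(mask, opening_iterations), opening_iterations)
  mask <- close_mask(mask, closing_iterations)
  labels <- label_components(mask)
  sizes <- component_sizes(labels)
  if (length(sizes) > 0L) {
    retain <- which(sizes >= min_component | seq_along(sizes) == which.max(sizes))
    mask <- array(labels %in% retain, dim(mask))
  }
  label_volume(mask, decomp$geometry, scan_time, check = FALSE)
}

#' Per-segment summary table of a region decomposition
#'
#' @param decomp A `region_decomposition`.
#' @return A data frame with one row per segment: `segment`, `rank` (1 =
#'   brightest), `max_intensity` (characteristic intensity), `n_voxels`.
#' @export
segment_table <- function(decomp) {
  stopifnot(inherits(decomp, "region_decomposition"))
  counts <- tabulate(decomp$assignment, nbins = decomp$k)
  data.frame(segment = seq_len(decomp$k),
             rank = match(seq_len(decomp$k), decomp$rank_order),
             max_intensity = decomp$segment_intensity,
             n_voxels = counts)
}

#' Estimate the gray-matter intensity level from an image
#'
#' Finds local modes of the intensity histogram and returns the center of
#' the brightest mode that carries at least `mass_frac` of all voxels. The
#' rationale: background and brain tissue are the major intensity classes,
#' gray matter is the brightest of them, and the tumor - though brighter
#' still - is a minority class that falls below the mass cutoff. The
#' estimator therefore assumes the tumor occupies less than `mass_frac` of
#' the image.
#'
#' @param image An [intensity_volume].
#' @param n_breaks Histogram resolution (default 64).
#' @param mass_frac Minimum voxel fraction (peak bin plus its two neighbors
#'   on each side) for a mode to count as a major class (default 0.05).
#' @return Estimated gray-matter level (intensity units), with the method
#'   recorded in the `"method"` attribute.
#' @export
estimate_gray_level <- function(image, n_breaks = 64L, mass_frac = 0.05) {
  stopifnot(inherits(image, "intensity_volume"))
  x <- as.vector(image$values)
  h <- graphics::hist(x, breaks = n_breaks, plot = FALSE)
  counts <- h$counts
  nb <- length(counts)
  peak_mass <- function(i) sum(counts[max(1, i - 2):min(nb, i + 2)]) / length(x)
  is_peak <- vapply(seq_len(nb), function(i) {
    counts[i] > 0 &&
      counts[i] >= (if (i > 1) counts[i - 1] else 0) &&
      counts[i] >= (if (i < nb) counts[i + 1] else 0)
  }, logical(1))
  major <- which(is_peak & vapply(seq_len(nb), peak_mass, numeric(1)) >= mass_frac)
  if (length(major) == 0L)
    stop("no major intensity mode found; supply gray_level explicitly")
  structure(h$mids[max(major)],
            method = "brightest major histogram mode")
}

#' Segment an intensity volume end to end
#'
#' Convenience wrapper: [decompose_regions()] then [extract_tumor_mask()],
#' estimating the gray level when not supplied.
#'
#' @inheritParams decompose_regions
#' @inheritParams extract_tumor_mask
#' @return A [label_volume].
#' @export
segment_tumor <- function(image, gray_level = NULL, k = 8L, n_bins = 8L,
                          seed = 1L, n_iter = 200L, opening_iterations = 1L,
                          closing_iterations = 1L, min_component = 10L,
                          scan_time = NA_real_) {
  if (is.null(gray_level)) gray_level <- estimate_gray_level(image)
  decomp <- decompose_regions(image, k = k, n_bins = n_bins, seed = seed,
                              n_iter = n_iter)
  extract_tumor_mask(decomp, gray_level,
                     opening_iterations = opening_iterations,
                     closing_iterations = closing_iterations,
                     min_component = min_component, scan_time = scan_time)
}
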