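# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# fine isotropic grid for geometry oracles
fine_acq <- function(n_slices = 5L, n = 64L, spacing = 1) {
  acquisition_params(spacing, spacing, spacing, c(n_slices, n, n))
}

# 2D digital disk as a slice mask
disk_slice <- function(n = 64L, radius = 20, center = NULL) {
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  m <- matrix(FALSE, n, n)
  inside <- (idx$i - center[1])^2 + (idx$j - center[2])^2 <= radius^2
  m[cbind(idx$i[inside], idx$j[inside])] <- TRUE
  m
}

# embed a single slice mask into a 3D label volume
single_slice_volume <- function(slice_mask, acq, slice = 2L, scan_time = 0) {
  mask <- array(FALSE, acq$grid_shape)
  mask[slice, , ] <- slice_mask
  label_volume(mask, acq, scan_time)
}

# random connected blob on an n x n slice: union of a few disks, then the
# largest component (guarantees connectivity)
random_blob <- function(n = 40L, n_disks = 3L, rmax = 8) {
  m <- matrix(FALSE, n, n)
  cx <- runif(n_disks, rmax + 2, n - rmax - 2)
  cy <- runif(n_disks, rmax + 2, n - rmax - 2)
  r <- runif(n_disks, 2, rmax)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  for (d in seq_len(n_disks)) {
    inside <- (idx$i - cx[d])^2 + (idx$j - cy[d])^2 <= r[d]^2
    m[cbind(idx$i[inside], idx$j[inside])] <- TRUE
  }
  m
}

# Exhaustive O(n^2) boundary-pair oracle for the bidimensional measurement.
# Written independently of the engine: plain double loops over all boundary
# pairs, same perpendicularity contract.
oracle_bidiameter <- function(slice_mask, spacing, perp_tol_deg = 5) {
  # boundary voxels of the largest 4-connected component
  comp <- ranovol:::largest_component(slice_mask)
  nr <- nrow(comp); nc <- ncol(comp)
  pts <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!comp[i, j]) next
    nb_out <- (i == 1 || !comp[i - 1, j]) || (i == nr || !comp[i + 1, j]) ||
      (j == 1 || !comp[i, j - 1]) || (j == nc || !comp[i, j + 1])
    if (nb_out) pts <- rbind(pts, c(i - 1, j - 1) * spacing)
  }
  n <- nrow(pts)
  if (n == 1L) return(list(d1_cm = spacing / 10, d2_cm = spacing / 10))
  best1 <- -1
  cand <- list()
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    d <- sqrt(sum((pts[a, ] - pts[b, ])^2))
    if (d > best1 + 1e-9) {
      best1 <- d
      cand <- list(list(p = pts[a, ], q = pts[b, ]))
    } else if (d >= best1 - 1e-9) {
      cand[[length(cand) + 1L]] <- list(p = pts[a, ], q = pts[b, ])
    }
  }
  # same tie-break contract as the engine: lexicographically smallest
  # ordered endpoint pair
  ordered <- lapply(cand, function(cc) {
    if (cc$p[1] < cc$q[1] || (cc$p[1] == cc$q[1] && cc$p[2] <= cc$q[2]))
      rbind(cc$p, cc$q) else rbind(cc$q, cc$p)
  })
  keys <- vapply(ordered, function(r)
    sprintf("%.6f|%.6f|%.6f|%.6f", r[1, 1], r[1, 2], r[2, 1], r[2, 2]),
    character(1))
  pick <- ordered[[order(keys)[1]]]
  pa <- pick[1, ]; pb <- pick[2, ]
  u <- (pb - pa) / best1
  sin_tol <- sin(perp_tol_deg * pi / 180) + 1e-12
  best2 <- -1
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    v <- pts[b, ] - pts[a, ]
    len <- sqrt(sum(v^2))
    if (len == 0) next
    if (abs(sum(v * u)) / len <= sin_tol && len > best2) best2 <- len
  }
  if (best2 < 0) best2 <- spacing
  list(d1_cm = best1 / 10, d2_cm = best2 / 10)
}

# Rank-statistic AUC by exhaustive pair counting (independent of binary_roc)
oracle_rank_auc <- function(pred, outcome) {
  pos <- pred[outcome == 1]
  neg <- pred[outcome == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small stable 4-class phantom subject with rendered intensities
phantom_subject <- function(noise_sd = 5, satellite_count = 0L, seed = 2L,
                            acq = NULL) {
  if (is.null(acq)) {
    acq <- if (satellite_count > 0L)
      acquisition_params(1, 2, 2, c(30L, 84L, 84L))
    else
      acquisition_params(1, 1, 1, c(30L, 64L, 64L))
  }
  spec <- trajectory_spec(c(12, 10, 8), "stable",
                          satellite_count = satellite_count,
                          scan_times = c(0, 0.5, 1, 1.5))
  generate_cohort(list(spec), acq, seed = seed, render_intensity = TRUE,
                  noise_sd = noise_sd)[[1]]
}
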