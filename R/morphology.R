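# Internal grid utilities: border checks, array shifts, morphological
# operators and connected-component labeling for 2D slices and 3D stacks.
# Connectivity is face-only (4 in 2D, 6 in 3D) throughout; that is the
# convention under which satellite lesions placed >= 5 mm away can never be
# labeled into the main component.

mask_touches_border <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    any(mask[1, ]) || any(mask[d[1], ]) || any(mask[, 1]) || any(mask[, d[2]])
  } else {
    any(mask[1, , ]) || any(mask[d[1], , ]) ||
      any(mask[, 1, ]) || any(mask[, d[2], ]) ||
      any(mask[, , 1]) || any(mask[, , d[3]])
  }
}

# zero-padded shift of a 2D/3D logical array by integer offset s
shift_mask <- function(mask, s) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    if (s[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - s[ax])
      dst[[ax]] <- src[[ax]] + s[ax]
    } else {
      src[[ax]] <- seq(1 - s[ax], d[ax])
      dst[[ax]] <- src[[ax]] + s[ax]
    }
    if (d[ax] + min(0, s[ax]) <= abs(s[ax])) return(out)
  }
  if (length(d) == 2L) {
    out[dst[[1]], dst[[2]]] <- mask[src[[1]], src[[2]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

face_offsets <- function(ndim) {
  offs <- list()
  for (ax in seq_len(ndim)) {
    for (s in c(-1L, 1L)) {
      o <- integer(ndim)
      o[ax] <- s
      offs[[length(offs) + 1L]] <- o
    }
  }
  offs
}

dilate_mask <- function(mask, iterations = 1L) {
  offs <- face_offsets(length(dim(mask)))
  for (i in seq_len(iterations)) {
    acc <- mask
    for (o in offs) acc <- acc | shift_mask(mask, o)
    mask <- acc
  }
  mask
}

erode_mask <- function(mask, iterations = 1L) {
  offs <- face_offsets(length(dim(mask)))
  for (i in seq_len(iterations)) {
    acc <- mask
    for (o in offs) acc <- acc & shift_mask(mask, o)
    mask <- acc
  }
  mask
}

close_mask <- function(mask, iterations = 1L) {
  if (iterations < 1L) return(mask)
  erode_mask(dilate_mask(mask, iterations), iterations)
}

# Face-connected component labeling by vectorized flood fill.
# Returns an integer array; 0 = background, components numbered from 1 in
# order of their smallest linear index (deterministic).
label_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  offs <- face_offsets(length(d))
  remaining <- which(mask)
  if (length(remaining) == 0L) return(labels)
  inside <- array(FALSE, d)
  inside[remaining] <- TRUE
  comp <- 0L
  while (length(remaining) > 0L) {
    comp <- comp + 1L
    seed <- remaining[1L]
    frontier <- array(FALSE, d)
    frontier[seed] <- TRUE
    member <- frontier
    repeat {
      grown <- member
      for (o in offs) grown <- grown | shift_mask(member, o)
      grown <- grown & inside
      if (sum(grown) == sum(member)) break
      member <- grown
    }
    labels[member] <- comp
    inside[member] <- FALSE
    remaining <- which(inside)
  }
  labels
}

component_sizes <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

largest_component <- function(mask) {
  labels <- label_components(mask)
  sizes <- component_sizes(labels)
  if (length(sizes) == 0L) return(mask)
  labels == which.max(sizes)  # which.max ties -> lowest label (deterministic)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b Binary arrays of identical dimension, or `label_volume` objects.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "label_volume")) a <- a$mask
  if (inherits(b, "label_volume")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
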