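# Simulated human operators for bidimensional measurement. Diameter reads
# are multiplicative: operator o, read r returns d * (1 + b_o + e_or) with a
# persistent per-operator bias b_o (inter-operator component) and a per-read
# error e_or (intra-operator component), truncated below at 10% of the true
# diameter so reads stay positive.

#' Operator read-noise model
#'
#' @param n_operators Number of operators (>= 1).
#' @param inter_sd_frac SD of the persistent per-operator fractional diameter
#'   bias (between-operator component).
#' @param intra_sd_frac SD of the per-read fractional diameter error
#'   (within-operator component).
#' @param seed Integer seed.
#' @return An object of class `operator_model`.
#' @export
operator_model <- function(n_operators = 3L, inter_sd_frac = 0.15,
                           intra_sd_frac = 0.05, seed = 1L) {
  if (inter_sd_frac < 0 || intra_sd_frac < 0)
    stop("operator noise SDs must be >= 0")
  stopifnot(n_operators >= 1)
  structure(list(n_operators = as.integer(n_operators),
                 inter_sd_frac = inter_sd_frac,
                 intra_sd_frac = intra_sd_frac,
                 seed = as.integer(seed)),
            class = "operator_model")
}

#' Draw persistent per-operator biases
#'
#' One fractional diameter bias per operator, `b_o ~ N(0, inter_sd_frac^2)`.
#' Exposed so a longitudinal simulation can hold each operator's bias fixed
#' across every scan of a series.
#'
#' @param model An [operator_model].
#' @param seed Optional seed overriding `model$seed`.
#' @return Numeric vector of length `n_operators`.
#' @export
operator_biases <- function(model, seed = NULL) {
  set.seed(if (is.null(seed)) model$seed else as.integer(seed))
  stats::rnorm(model$n_operators, 0, model$inter_sd_frac)
}

#' Simulate operator reads of a bidimensional measurement
#'
#' Applies the operator noise model to a true [rano_measurement]: each
#' operator's read scales both diameters by `(1 + b_o + e_or)` (truncated
#' below at 10% of the true value) and the product is recomputed from the
#' noisy diameters, so products inherit the right-skew of multiplicative
#' diameter noise.
#'
#' @param true_measurement A [rano_measurement] with positive diameters.
#' @param model An [operator_model].
#' @param n_reads Reads per operator (>= 1); reads within an operator share
#'   the operator bias but draw independent intra-operator errors.
#' @param biases Optional precomputed per-operator biases (from
#'   [operator_biases()]); defaults to drawing them from `model$seed`.
#' @param seed Optional seed for the intra-operator draws, overriding
#'   `model$seed`.
#' @return A data frame with one row per operator x read: `operator`, `read`,
#'   `slice_index`, `d1_cm`, `d2_cm`, `product_cm2`.
#' @export
simulate_operator_reads <- function(true_measurement, model, n_reads = 1L,
                                    biases = NULL, seed = NULL) {
  stopifnot(inherits(true_measurement, "rano_measurement"),
            inherits(model, "operator_model"), n_reads >= 1)
  d1 <- true_measurement$d1
  d2 <- true_measurement$d2
  if (d1 <= 0 || d2 <= 0) stop("true diameters must be positive")
  set.seed(if (is.null(seed)) model$seed else as.integer(seed))
  if (is.null(biases)) {
    biases <- stats::rnorm(model$n_operators, 0, model$inter_sd_frac)
  } else {
    stopifnot(length(biases) == model$n_operators)
  }
  rows <- expand.grid(read = seq_len(n_reads),
                      operator = seq_len(model$n_operators))[, 2:1]
  e1 <- stats::rnorm(nrow(rows), 0, model$intra_sd_frac)
  e2 <- stats::rnorm(nrow(rows), 0, model$intra_sd_frac)
  s1 <- pmax(1 + biases[rows$operator] + e1, 0.1)
  s2 <- pmax(1 + biases[rows$operator] + e2, 0.1)
  data.frame(operator = rows$operator, read = rows$read,
             slice_index = true_measurement$slice_index,
             d1_cm = d1 * s1, d2_cm = d2 * s2,
             product_cm2 = d1 * s1 * d2 * s2)
}
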