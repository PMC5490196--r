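#' Distance-dependent jump probability of the heterogeneous model
#'
#' In the heterogeneous shifting level model the per-step jump probability
#' is a function of the genomic distance `d` between adjacent windows:
#'
#' `eta(d) = theta + (1 - theta) * exp(log(theta) / (d / d_norm))`
#'
#' `theta` is the baseline jump probability and `d_norm` the distance scale
#' at which the probability starts to grow: for `d << d_norm` the
#' probability stays at `theta`; as `d` grows beyond `d_norm` it rises
#' monotonically toward 1. The exponent is evaluated as
#' `log(theta) * d_norm / d` (algebraically identical) and the `d = 0` case
#' returns the analytic limit `theta`, since `log(theta) < 0` drives the
#' exponential to zero.
#'
#' @param d Genomic distance(s) in bp, >= 0 (vectorised).
#' @param theta Baseline jump probability in (0, 1).
#' @param d_norm Distance normalization parameter in bp, > 0.
#'
#' @return Jump probabilities in \[theta, 1), same length as `d`.
#' @export
#' @examples
#' transition_probability(c(0, 1e5, 2e5), theta = 0.1, d_norm = 1e5)
transition_probability <- function(d, theta, d_norm) {
  if (!(theta > 0 && theta < 1))
    stop("theta must lie strictly in (0, 1)")
  if (!(d_norm > 0)) stop("d_norm must be positive")
  if (any(d < 0)) stop("distances must be non-negative")
  eta <- theta + (1 - theta) * exp(log(theta) * d_norm / d)
  eta[d == 0] <- theta
  eta
}

#' Per-step heterogeneous transition matrices
#'
#' One K x K stochastic matrix per step, identical in form to
#' [build_transition_matrix()] but with the homogeneous `eta` replaced by
#' `eta(d_i)` from [transition_probability()].
#'
#' @param grid Level grid (list with `levels`, `prior`).
#' @param theta Baseline jump probability in (0, 1).
#' @param d_norm Distance normalization parameter (bp).
#' @param distances Per-step distances `d_i` (bp), length N - 1.
#'
#' @return List of `length(distances)` stochastic K x K matrices.
#' @export
build_heterogeneous_transitions <- function(grid, theta, d_norm, distances) {
  eta <- transition_probability(distances, theta, d_norm)
  lapply(eta, function(e) build_transition_matrix(grid, e))
}

#' Inter-window gap distances of a profile
#'
#' The distance between window i and window i-1 is the genomic gap
#' `start_i - end_(i-1)`, floored at 0 for adjacent or bookended windows,
#' so contiguously tiled profiles have all distances 0 and the
#' heterogeneous model reduces to the homogeneous one.
#'
#' @param profile A [genomic_profile].
#' @return Numeric vector of length N - 1 (bp).
#' @export
profile_distances <- function(profile) {
  stopifnot(inherits(profile, "genomic_profile"))
  n <- nrow(profile)
  if (n < 2) return(numeric(0))
  pmax(0, profile$start[-1] - profile$end[-n])
}

#' Segment a sparse log2 profile with the heterogeneous shifting level model
#'
#' Same pipeline as [slm_segment()], but the Viterbi recursion consumes a
#' per-step transition matrix built from the jump probability
#' `eta(d_i)` of [transition_probability()], where `d_i` is the genomic gap
#' between consecutive windows ([profile_distances()]). On a profile with
#' all gaps zero the result is bit-identical to
#' `slm_segment(profile, eta = theta)`.
#'
#' Smaller `d_norm` makes jumps across a given gap more likely, raising the
#' resolution for small events at the cost of more false positives.
#'
#' @param profile A `LOG2RATIO` [genomic_profile]; the window coordinates
#'   supply the inter-window distances.
#' @param theta Baseline jump probability (default `1e-5`).
#' @param d_norm Distance normalization parameter in bp (default `1e5`).
#' @param omega,n_levels,min_seg_windows See [slm_segment()].
#'
#' @return An `slm_segmentation` (see [slm_segment()]).
#' @export
hslm_segment <- function(profile, theta = 1e-5, d_norm = 1e5, omega = 0.3,
                         n_levels = 41, min_seg_windows = 1) {
  stopifnot(inherits(profile, "genomic_profile"))
  if (!(theta > 0 && theta < 1))
    stop("theta must lie strictly in (0, 1)")
  if (!(d_norm > 0)) stop("d_norm must be positive")
  n <- nrow(profile)
  eta <- if (n >= 2)
    transition_probability(profile_distances(profile), theta, d_norm)
  else theta
  .segment_core(profile, eta, omega, n_levels, min_seg_windows)
}
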