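#' Estimate shifting-level-model parameters from a log2 profile
#'
#' The shifting level model writes the observed signal as
#' `x_i = m_i + eps_i`, where `m_i` is a piecewise-constant latent mean that,
#' with probability `eta` per step, jumps to a fresh `N(mu, sigma2_m)` draw,
#' and `eps_i ~ N(0, sigma2_eps)` is white noise. This moment estimator
#' sets `mu` to the median of the data and estimates the white-noise
#' variance from a robust (MAD-based) scale of the first differences:
#' differencing cancels the piecewise-constant mean away from breakpoints,
#' and the median absolute deviation ignores the rare shift-crossing
#' differences, so `mad(diff(x))^2 / 2` identifies `sigma2_eps` directly.
#' The parameter `omega` is the noise share of the total model variance,
#' so the total is recovered as `sigma2_total = sigma2_eps / omega` and the
#' level variance as `sigma2_m = (1 - omega) * sigma2_total`.
#'
#' The continuous latent level is discretised on a grid of `n_levels`
#' candidate means placed at the data quantiles between 0.005 and 0.995
#' (deduplicated, re-spaced evenly over the same range if quantiles
#' collapse), with prior weight proportional to the `N(mu, sigma2_m)`
#' density at each level.
#'
#' @param profile A `LOG2RATIO` [genomic_profile] or a bare numeric vector.
#' @param omega Fraction of the total variance assigned to the white noise,
#'   in (0, 1).
#' @param eta Per-step jump probability in (0, 1); stored for downstream use.
#' @param n_levels Number of grid levels K (>= 2).
#'
#' @return An object of class `slm_parameters`: list with `mu`, `sigma2_m`,
#'   `sigma2_eps`, `eta`, `omega`, `n_levels`, `degenerate` flag, and
#'   `grid` (list with ascending `levels` and normalized `prior`).
#' @export
estimate_parameters <- function(profile, omega = 0.3, eta = 1e-5,
                                n_levels = 41) {
  x <- if (inherits(profile, "genomic_profile")) profile$value else profile
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)),
            omega > 0, omega < 1, n_levels >= 2)
  mu <- stats::median(x)

  s2_eps <- if (length(x) >= 2) (stats::mad(diff(x))^2) / 2 else 0
  # mad(diff) is zero when >50% of steps are flat (e.g. noise-free step
  # profiles); fall back to the overall variance, which still sees shifts
  s2_total <- if (s2_eps > 0) s2_eps / omega else stats::var(x)
  if (!is.finite(s2_total) || is.na(s2_total) || s2_total == 0) {
    return(structure(list(mu = mu, sigma2_m = NA_real_, sigma2_eps = NA_real_,
                          eta = eta, omega = omega, n_levels = n_levels,
                          degenerate = TRUE,
                          grid = list(levels = mu, prior = 1)),
                     class = "slm_parameters"))
  }
  sigma2_eps <- omega * s2_total
  sigma2_m <- (1 - omega) * s2_total

  qs <- stats::quantile(x, probs = seq(0.005, 0.995, length.out = n_levels),
                        names = FALSE, type = 7)
  if (length(unique(qs)) < n_levels)
    qs <- seq(qs[1], qs[n_levels], length.out = n_levels)
  if (qs[1] == qs[n_levels]) {
    # all mass at one value but variance positive cannot happen; guard anyway
    qs <- mu + (seq_len(n_levels) - (n_levels + 1) / 2) * sqrt(s2_total)
  }
  lp <- stats::dnorm(qs, mean = mu, sd = sqrt(sigma2_m), log = TRUE)
  p <- exp(lp - max(lp))
  p <- pmax(p, 1e-300)
  p <- p / sum(p)

  structure(list(mu = mu, sigma2_m = sigma2_m, sigma2_eps = sigma2_eps,
                 eta = eta, omega = omega, n_levels = n_levels,
                 degenerate = FALSE,
                 grid = list(levels = qs, prior = p)),
            class = "slm_parameters")
}

#' @export
print.slm_parameters <- function(x, ...) {
  cat(sprintf(paste0("slm_parameters: mu=%.4g sigma2_m=%.4g sigma2_eps=%.4g",
                     " eta=%.3g omega=%.2f K=%d%s\n"),
              x$mu, x$sigma2_m, x$sigma2_eps, x$eta, x$omega, x$n_levels,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Homogeneous transition matrix of the level chain
#'
#' The jump indicator `z_i` equals 1 with probability `eta`; on a jump the
#' chain lands on grid level k with the prior probability `pi_k`,
#' independently of the origin. The Markov embedding is
#' `A[j, k] = (1 - eta) * 1[j == k] + eta * pi_k`; every row sums to 1 and
#' every diagonal entry is at least `1 - eta`.
#'
#' @param grid Level grid: list with `levels` and `prior` (e.g.
#'   `estimate_parameters(...)$grid`).
#' @param eta Jump probability in (0, 1\] (0 allowed: never jump).
#'
#' @return A K x K stochastic matrix.
#' @export
build_transition_matrix <- function(grid, eta) {
  prior <- grid$prior
  K <- length(prior)
  stopifnot(K >= 1, eta >= 0, eta <= 1,
            abs(sum(prior) - 1) < 1e-8, all(prior > 0))
  A <- matrix(rep(eta * prior, each = K), K, K)
  diag(A) <- diag(A) + (1 - eta)
  A
}

# Build the (N-1) x K log stay/jump matrices consumed by the C++ recursion.
# eta may be a scalar (homogeneous) or a length N-1 vector (heterogeneous);
# entries are log((1-eta_i) + eta_i*pi_k) and log(eta_i*pi_k), bitwise equal
# to logs of the build_transition_matrix entries.
.step_log_matrices <- function(prior, eta, n) {
  K <- length(prior)
  if (length(eta) == 1) eta <- rep(eta, n - 1)
  stopifnot(length(eta) == n - 1, all(eta >= 0 & eta <= 1))
  ep <- outer(eta, prior)                      # eta_i * pi_k
  list(log_stay = log((1 - eta) + ep), log_jump = log(ep))
}

.emission_matrix <- function(x, levels, sigma2_eps) {
  sd <- sqrt(sigma2_eps)
  vapply(levels, function(l) stats::dnorm(x, mean = l, sd = sd, log = TRUE),
         numeric(length(x)))
}

#' Viterbi decoding of the discretised shifting level model
#'
#' Returns the jointly most probable sequence of grid-level indices under
#' the level-chain prior, the (possibly step-heterogeneous) transition
#' model, and Gaussian emissions `N(x_i; level_k, sigma2_eps)`, maximising
#' `log pi(s_1) + sum log A_i[s_(i-1), s_i] + sum log N(x_i; level_(s_i))`
#' in log space. Ties are broken toward the lower level index.
#'
#' @param x Numeric log2-ratio vector (or a `LOG2RATIO` [genomic_profile]).
#' @param grid Level grid (list with `levels`, `prior`).
#' @param eta Jump probability: scalar for the homogeneous model or a
#'   vector of length `N - 1` with one probability per step (heterogeneous).
#' @param sigma2_eps Positive white-noise variance.
#'
#' @return Integer vector of 1-based level indices, one per window.
#' @export
viterbi_decode <- function(x, grid, eta, sigma2_eps) {
  if (inherits(x, "genomic_profile")) x <- x$value
  n <- length(x)
  K <- length(grid$levels)
  stopifnot(n >= 1, K >= 1, length(grid$prior) == K)
  if (!is.finite(sigma2_eps) || sigma2_eps <= 0)
    stop("sigma2_eps must be positive and finite")
  emis <- .emission_matrix(x, grid$levels, sigma2_eps)
  if (n == 1) return(which.max(log(grid$prior) + emis[1, ]))
  sm <- .step_log_matrices(grid$prior, eta, n)
  viterbi_path_structured(emis, log(grid$prior), sm$log_stay, sm$log_jump)
}

# collapse a decoded path into segments with empirical means
.collapse_path <- function(path, x) {
  r <- rle(path)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1
  means <- vapply(seq_along(start),
                  function(i) mean(x[start[i]:end[i]]), numeric(1))
  data.frame(start = start, end = end, n_windows = r$lengths,
             mean_level = means)
}

# merge segments shorter than min_windows into the neighbour with the
# closer mean; the left neighbour wins exact ties
.merge_short_segments <- function(segs, x, min_windows) {
  while (nrow(segs) > 1 && any(segs$n_windows < min_windows)) {
    short <- which(segs$n_windows < min_windows)
    i <- short[which.min(segs$n_windows[short])]
    into <- if (i == 1) 2
    else if (i == nrow(segs)) i - 1
    else {
      dl <- abs(segs$mean_level[i] - segs$mean_level[i - 1])
      dr <- abs(segs$mean_level[i] - segs$mean_level[i + 1])
      if (dl <= dr) i - 1 else i + 1
    }
    a <- min(i, into); b <- max(i, into)
    segs$end[a] <- segs$end[b]
    segs$n_windows[a] <- segs$end[a] - segs$start[a] + 1
    segs$mean_level[a] <- mean(x[segs$start[a]:segs$end[a]])
    segs <- segs[-b, , drop = FALSE]
    rownames(segs) <- NULL
  }
  segs
}

# shared segmentation pipeline for the homogeneous and heterogeneous models
.segment_core <- function(profile, eta, omega, n_levels, min_seg_windows) {
  x <- if (inherits(profile, "genomic_profile")) profile$value else profile
  n <- length(x)
  params <- estimate_parameters(x, omega = omega,
                                eta = if (length(eta) == 1) eta else NA_real_,
                                n_levels = n_levels)
  if (params$degenerate || n == 1) {
    segs <- data.frame(start = 1, end = n, n_windows = n,
                       mean_level = mean(x))
    seg <- new_segmentation(segs, x)
    attr(seg, "parameters") <- params
    return(seg)
  }
  path <- viterbi_decode(x, params$grid, eta, params$sigma2_eps)
  segs <- .collapse_path(path, x)
  if (min_seg_windows > 1)
    segs <- .merge_short_segments(segs, x, min_seg_windows)
  seg <- new_segmentation(segs, x)
  attr(seg, "parameters") <- params
  seg
}

#' Segment a log2 profile with the homogeneous shifting level model
#'
#' Composes [estimate_parameters()], the homogeneous transition model and
#' [viterbi_decode()], then collapses consecutive equal decoded levels into
#' segments. Each segment's reported `mean_level` is the arithmetic mean of
#' its windows' observed values (not the grid level). Segments shorter than
#' `min_seg_windows` are merged into the neighbour with the closer mean.
#' Decoding is deterministic: no randomness is involved.
#'
#' @param profile A `LOG2RATIO` [genomic_profile] or numeric vector.
#' @param omega Noise share of the total variance (see
#'   [estimate_parameters()]).
#' @param eta Per-step jump probability (default `1e-5`; smaller values
#'   yield fewer, larger segments).
#' @param n_levels Level-grid size K.
#' @param min_seg_windows Minimum segment length in windows (default 1:
#'   no merging).
#'
#' @return An `slm_segmentation`: list with per-window `levels`, a
#'   `segments` data frame (`start`, `end` window indices, `n_windows`,
#'   `mean_level`) and `breakpoints` (indices i where the level changes
#'   between windows i-1 and i). The fitted `slm_parameters` are attached
#'   as attribute `"parameters"`.
#' @export
#' @examples
#' sim <- simulate_profile(n_altered = 50, total_windows = 2000, seed = 1)
#' seg <- slm_segment(sim$profile)
#' seg$segments
slm_segment <- function(profile, omega = 0.3, eta = 1e-5, n_levels = 41,
                        min_seg_windows = 1) {
  stopifnot(length(eta) == 1, eta > 0, eta < 1)
  .segment_core(profile, eta, omega, n_levels, min_seg_windows)
}

#' Call copy-number variants from a segmentation
#'
#' Segments whose mean level falls at or below `loss_threshold` are called
#' LOSS, at or above `gain_threshold` GAIN, otherwise NEUTRAL. Adjacent
#' segments in the same altered state are merged into one call whose mean
#' is the window-count-weighted mean of its parts. Only altered (LOSS or
#' GAIN) calls are returned, in 0-based half-open bp coordinates.
#'
#' The defaults (-0.5, +0.3) bracket the theoretical diploid log2 levels of
#' a one-copy loss (-1) and a single-copy gain (+0.585) with noise margin.
#'
#' @param seg An `slm_segmentation`.
#' @param profile The segmented [genomic_profile] (for coordinates).
#' @param loss_threshold Log2 level at or below which a segment is a LOSS
#'   (must be < 0).
#' @param gain_threshold Log2 level at or above which a segment is a GAIN
#'   (must be > 0).
#'
#' @return Data frame with columns `chrom`, `start`, `end`, `copy_state`
#'   (`"LOSS"`/`"GAIN"`), `mean_level`, `n_windows`; zero rows when no
#'   segment crosses a threshold.
#' @export
call_cnvs <- function(seg, profile, loss_threshold = -0.5,
                      gain_threshold = 0.3) {
  stopifnot(inherits(seg, "slm_segmentation"),
            inherits(profile, "genomic_profile"),
            loss_threshold < 0, gain_threshold > 0)
  if (length(seg$levels) != nrow(profile))
    stop("segmentation does not match profile length")
  s <- seg$segments
  state <- ifelse(s$mean_level <= loss_threshold, "LOSS",
                  ifelse(s$mean_level >= gain_threshold, "GAIN", "NEUTRAL"))
  calls <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), copy_state = character(0),
                      mean_level = numeric(0), n_windows = integer(0),
                      stringsAsFactors = FALSE)
  i <- 1
  while (i <= nrow(s)) {
    if (state[i] == "NEUTRAL") { i <- i + 1; next }
    j <- i
    while (j < nrow(s) && state[j + 1] == state[i]) j <- j + 1
    nw <- sum(s$n_windows[i:j])
    calls <- rbind(calls, data.frame(
      chrom = profile$chrom[1],
      start = profile$start[s$start[i]],
      end = profile$end[s$end[j]],
      copy_state = state[i],
      mean_level = sum(s$mean_level[i:j] * s$n_windows[i:j]) / nw,
      n_windows = nw, stringsAsFactors = FALSE))
    i <- j + 1
  }
  rownames(calls) <- NULL
  calls
}
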