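#' Simulate a dense genomic profile with one embedded copy-number event
#'
#' Generates a log2-ratio profile of `total_windows` contiguously tiled
#' windows in which `n_altered` consecutive windows carry a mean shift and
#' the remaining `total_windows - n_altered` windows are diploid
#' background. Background windows are drawn `N(0, noise_sd^2)` and altered
#' windows `N(shift, noise_sd^2)`, with the shift fixed at the theoretical
#' diploid log2 levels: -1 for a one-copy loss (`ONE_COPY`) and
#' `log2(3/2) ~ +0.585` for a single-copy gain (`THREE_COPY`). The event is
#' placed uniformly at random with at least one background window on each
#' flank. A fixed seed gives byte-identical output.
#'
#' @param n_altered Event length N in windows; 0 gives a pure-noise profile.
#' @param total_windows Profile length (default 10000).
#' @param event_type `"ONE_COPY"` (loss) or `"THREE_COPY"` (gain).
#' @param noise_sd Per-window log2 noise standard deviation (> 0); see
#'   [coverage_noise_sd()] to derive it from coverage and window size.
#' @param window_bp Window size in bp (100/200/500/1000 are the usual
#'   choices; any positive value works).
#' @param seed Optional RNG seed.
#' @param chrom Chromosome name of the synthetic profile.
#'
#' @return List with `profile` (a `LOG2RATIO` [genomic_profile]) and
#'   `truth` (class `cnv_truth`): `intervals` (data frame with `chrom`,
#'   `start`, `end` bp, `copy_state`, `start_index`, `end_index`, `shift`),
#'   `breakpoints` (window indices i where the true mean changes between
#'   windows i-1 and i), and the generating parameters.
#' @export
#' @examples
#' sim <- simulate_profile(n_altered = 100, seed = 7)
#' sim$truth$breakpoints
simulate_profile <- function(n_altered = 100, total_windows = 10000,
                             event_type = c("ONE_COPY", "THREE_COPY"),
                             noise_sd = 0.2, window_bp = 1000, seed = NULL,
                             chrom = "chrS") {
  event_type <- match.arg(event_type)
  stopifnot(total_windows >= 1, n_altered >= 0, noise_sd > 0, window_bp > 0)
  if (n_altered > 0 && n_altered >= total_windows - 1)
    stop("n_altered must leave at least one background window per flank")
  if (!is.null(seed)) set.seed(seed)

  shift <- if (event_type == "ONE_COPY") -1 else log2(3 / 2)
  if (n_altered > 0) {
    s <- sample.int(total_windows - n_altered - 1, 1) + 1  # in [2, T-N]
    e <- s + n_altered - 1
  }
  values <- stats::rnorm(total_windows, 0, noise_sd)
  if (n_altered > 0) values[s:e] <- values[s:e] + shift

  start <- (seq_len(total_windows) - 1) * window_bp
  profile <- genomic_profile(chrom, start, start + window_bp, values,
                             scale = "LOG2RATIO")
  truth <- if (n_altered > 0) {
    structure(list(
      intervals = data.frame(
        chrom = chrom, start = start[s], end = start[e] + window_bp,
        copy_state = if (event_type == "ONE_COPY") "LOSS" else "GAIN",
        start_index = s, end_index = e, shift = shift,
        stringsAsFactors = FALSE),
      breakpoints = c(s, e + 1),
      n_altered = n_altered, event_type = event_type,
      noise_sd = noise_sd, shift = shift), class = "cnv_truth")
  } else {
    structure(list(intervals = data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      copy_state = character(0), start_index = integer(0),
      end_index = integer(0), shift = numeric(0), stringsAsFactors = FALSE),
      breakpoints = integer(0), n_altered = 0L, event_type = event_type,
      noise_sd = noise_sd, shift = shift), class = "cnv_truth")
  }
  list(profile = profile, truth = truth)
}

#' Simulate a sparse (exome-like) profile with random inter-window gaps
#'
#' As [simulate_profile()], but consecutive windows are separated by random
#' genomic gaps drawn log-uniformly on \[1, `max_gap`\] bp (rounded to
#' integer bp; the continuous distribution has mean
#' `(max_gap - 1) / log(max_gap)`). Values and event placement are drawn
#' before the gaps, so with the same seed the value sequence matches the
#' dense simulator and `max_gap = 0` reproduces it exactly.
#'
#' @inheritParams simulate_profile
#' @param max_gap Maximum inter-window gap in bp; 0 disables gaps.
#' @param gap_at_breakpoints Optional fixed gap (bp) imposed at the true
#'   event boundaries after the random draw, to place a shift exactly at a
#'   large gap.
#'
#' @return As [simulate_profile()]; `truth` additionally carries
#'   `breakpoint_gaps`, the gap (bp) immediately preceding each true
#'   breakpoint.
#' @export
simulate_sparse_profile <- function(n_altered = 100, total_windows = 10000,
                                    event_type = c("ONE_COPY", "THREE_COPY"),
                                    noise_sd = 0.2, window_bp = 100,
                                    seed = NULL, chrom = "chrS",
                                    max_gap = 1e5,
                                    gap_at_breakpoints = NULL) {
  event_type <- match.arg(event_type)
  sim <- simulate_profile(n_altered = n_altered,
                          total_windows = total_windows,
                          event_type = event_type, noise_sd = noise_sd,
                          window_bp = window_bp, seed = seed, chrom = chrom)
  n <- total_windows
  gaps <- if (max_gap > 0 && n > 1)
    round(exp(stats::runif(n - 1, 0, log(max_gap))))
  else rep(0, max(0, n - 1))
  if (!is.null(gap_at_breakpoints) && length(sim$truth$breakpoints))
    gaps[sim$truth$breakpoints - 1] <- gap_at_breakpoints

  start <- cumsum(c(0, gaps + window_bp))[seq_len(n)]
  profile <- genomic_profile(chrom, start, start + window_bp,
                             sim$profile$value, scale = "LOG2RATIO")
  truth <- sim$truth
  if (nrow(truth$intervals)) {
    truth$intervals$start <- start[truth$intervals$start_index]
    truth$intervals$end <- start[truth$intervals$end_index] + window_bp
    truth$breakpoint_gaps <- gaps[truth$breakpoints - 1]
  } else {
    truth$breakpoint_gaps <- numeric(0)
  }
  list(profile = profile, truth = truth)
}

#' Expected log2 noise level for a given coverage and window size
#'
#' With read length 100 bp, a window of `window_bp` at `coverage`-fold
#' depth receives on average `lambda = coverage * window_bp / read_length`
#' reads. Modelling the window count as Poisson(lambda), the delta method
#' gives the standard deviation of its log2-ratio around 0 as
#' `1 / (ln(2) * sqrt(lambda))`, which ties the simulator's Gaussian noise
#' scale to the coverage / window-size grid of read-depth experiments.
#'
#' @param coverage Fold sequencing coverage (> 0).
#' @param window_bp Window size in bp (> 0).
#' @param read_length Read length in bp (default 100).
#'
#' @return The log2-scale noise standard deviation. When `lambda < 10` the
#'   normal approximation is poor; a warning is emitted and the result
#'   carries attribute `low_coverage = TRUE`.
#' @export
#' @examples
#' coverage_noise_sd(50, 1000)  # ~0.0645
coverage_noise_sd <- function(coverage, window_bp, read_length = 100) {
  stopifnot(coverage > 0, window_bp > 0, read_length > 0)
  lambda <- coverage * window_bp / read_length
  sd <- 1 / (log(2) * sqrt(lambda))
  if (lambda < 10) {
    warning("expected reads per window (", lambda,
            ") is low; the Gaussian log2 noise approximation is poor")
    attr(sd, "low_coverage") <- TRUE
  }
  sd
}
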