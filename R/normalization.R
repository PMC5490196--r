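#' GC-content and mappability correction of window read counts
#'
#' Median-ratio correction stratified by GC content: windows are binned by
#' GC fraction and each included window's count is rescaled by
#' `global median / stratum median`, so every stratum's median equals the
#' global median afterwards. Strata occupied by fewer than `min_stratum`
#' windows inherit the global median (no correction). Windows whose
#' mappable fraction falls below `map_min` are flagged excluded and left
#' untouched; they should be dropped before segmentation.
#'
#' @param counts Non-negative read counts, one per window.
#' @param gc GC fraction per window in \[0, 1\].
#' @param mappability Optional mappable fraction per window in \[0, 1\];
#'   `NULL` disables the mappability filter.
#' @param gc_bin_width Width of the GC strata (default 0.01, i.e. 1%).
#' @param map_min Minimum mappable fraction for a window to be kept.
#' @param min_stratum Minimum windows per stratum before correction applies.
#'
#' @return List with `counts` (corrected; excluded windows unchanged),
#'   `excluded` (logical), and `factors` (per-window scale factor applied).
#' @export
gc_mappability_correct <- function(counts, gc, mappability = NULL,
                                   gc_bin_width = 0.01, map_min = 0.5,
                                   min_stratum = 20) {
  n <- length(counts)
  stopifnot(length(gc) == n, all(counts >= 0), all(gc >= 0 & gc <= 1),
            gc_bin_width > 0)
  excluded <- rep(FALSE, n)
  if (!is.null(mappability)) {
    stopifnot(length(mappability) == n,
              all(mappability >= 0 & mappability <= 1))
    excluded <- mappability < map_min
  }
  if (all(excluded)) stop("all windows excluded by the mappability filter")
  keep <- !excluded
  global_med <- stats::median(counts[keep])
  if (global_med == 0)
    stop("degenerate input: global median read count is zero")

  bin <- pmin(floor(gc / gc_bin_width), floor(1 / gc_bin_width))
  factors <- rep(1, n)
  for (b in unique(bin[keep])) {
    idx <- which(keep & bin == b)
    if (length(idx) < min_stratum) next
    med <- stats::median(counts[idx])
    if (med > 0) factors[idx] <- global_med / med
  }
  out <- counts
  out[keep] <- counts[keep] * factors[keep]
  list(counts = out, excluded = excluded, factors = factors)
}

#' Log2-transform corrected read counts
#'
#' Computes `log2(count / reference)` per window. Zero counts are replaced
#' by a half-count pseudo-count (0.5 by default) before the transform, so
#' deep deletions stay visible as strongly negative finite values; such
#' windows are flagged.
#'
#' @param counts Non-negative (corrected) read counts.
#' @param reference Positive expected count: a scalar (global median by
#'   default) or one value per window.
#' @param pseudo Pseudo-count substituted for zero counts.
#'
#' @return List with `log2` (the log2-ratio vector) and `zero_flag`
#'   (logical marker of pseudo-counted windows).
#' @export
log2_transform <- function(counts, reference = NULL, pseudo = 0.5) {
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (is.null(reference)) reference <- stats::median(counts)
  if (any(reference <= 0)) stop("reference must be positive")
  stopifnot(length(reference) == 1 || length(reference) == length(counts))
  zero_flag <- counts == 0
  counts[zero_flag] <- pseudo
  list(log2 = log2(counts / reference), zero_flag = zero_flag)
}

#' Normalize a read-count profile to a log2-ratio profile
#'
#' Full pipeline: mappability exclusion, GC median-ratio correction,
#' log2 transform against the global median, and optional median-centering.
#' GC correction requires a `gc` column on the profile and the mappability
#' filter a `mappability` column; each step is skipped when its covariate
#' is absent. Excluded windows are removed from the returned profile (their
#' original row indices are reported so segments can be mapped back).
#'
#' @param profile A [genomic_profile] on the `RC` scale, optionally carrying
#'   `gc` and `mappability` columns.
#' @param gc_bin_width,map_min,min_stratum See [gc_mappability_correct()].
#' @param pseudo See [log2_transform()].
#' @param center Median-center the log2 profile (default `TRUE`).
#'
#' @return List with `profile` (a `LOG2RATIO` [genomic_profile] keeping the
#'   original window coordinates), `excluded_index` (row indices of dropped
#'   windows in the input), and `zero_flag` (per retained window).
#' @export
normalize_profile <- function(profile, gc_bin_width = 0.01, map_min = 0.5,
                              min_stratum = 20, pseudo = 0.5, center = TRUE) {
  stopifnot(inherits(profile, "genomic_profile"))
  if (profile_scale(profile) != "RC")
    stop("normalize_profile expects a read-count (RC) profile")
  counts <- profile$value
  excluded <- rep(FALSE, nrow(profile))
  if (!is.null(profile$gc)) {
    corr <- gc_mappability_correct(counts, profile$gc, profile$mappability,
                                   gc_bin_width = gc_bin_width,
                                   map_min = map_min,
                                   min_stratum = min_stratum)
    counts <- corr$counts
    excluded <- corr$excluded
  } else if (!is.null(profile$mappability)) {
    excluded <- profile$mappability < map_min
    if (all(excluded)) stop("all windows excluded by the mappability filter")
  }
  keep <- which(!excluded)
  lt <- log2_transform(counts[keep], pseudo = pseudo)
  l2 <- lt$log2
  if (center) l2 <- l2 - stats::median(l2)
  out <- genomic_profile(profile$chrom[keep], profile$start[keep],
                         profile$end[keep], l2, scale = "LOG2RATIO")
  list(profile = out, excluded_index = which(excluded),
       zero_flag = lt$zero_flag)
}
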