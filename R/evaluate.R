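#' Window distances between predicted and true breakpoints
#'
#' For every true breakpoint, the distance (in windows) to the nearest
#' predicted breakpoint, and symmetrically for every prediction the
#' distance to the nearest truth. A side with no counterpart records `Inf`
#' (a miss).
#'
#' @param predicted Integer window indices of predicted breakpoints (e.g.
#'   `seg$breakpoints`).
#' @param truth True breakpoint indices, or a `cnv_truth` object.
#'
#' @return List with `truth_to_pred` and `pred_to_truth` distance vectors.
#' @export
breakpoint_distances <- function(predicted, truth) {
  if (inherits(truth, "cnv_truth")) truth <- truth$breakpoints
  predicted <- as.numeric(predicted); truth <- as.numeric(truth)
  nearest <- function(from, to) {
    if (length(from) == 0) return(numeric(0))
    if (length(to) == 0) return(rep(Inf, length(from)))
    vapply(from, function(b) min(abs(b - to)), numeric(1))
  }
  list(truth_to_pred = nearest(truth, predicted),
       pred_to_truth = nearest(predicted, truth))
}

#' Breakpoint ROC curve and AUC over a sensitivity-parameter sweep
#'
#' Viterbi decoding yields hard breakpoint calls with no per-call score, so
#' ROC operating points are generated by sweeping the model's jump
#' probability (`eta` for the homogeneous model, `theta` for the
#' heterogeneous one). For each sweep value the segmenter runs on every
#' profile and counts are pooled: TPR is the fraction of true breakpoints
#' with a prediction within `tolerance_windows`; FPR divides the
#' predictions farther than the tolerance from any truth by the number of
#' eligible negative positions (candidate breakpoint positions not within
#' the tolerance of any true breakpoint). The curve is anchored at (0,0)
#' and (1,1) and integrated by the trapezoid rule, so a segmenter that
#' predicts nothing scores the chance-line AUC of 0.5.
#'
#' @param profiles List of simulation results, each a list with `profile`
#'   and `truth` (as returned by [simulate_profile()]).
#' @param segmenter Function `(profile, sweep_value)` returning an
#'   `slm_segmentation` or a vector of breakpoint indices.
#' @param sweep Numeric vector (length >= 2) of parameter values.
#' @param tolerance_windows Match tolerance in windows (default 2).
#'
#' @return List with `points` (data frame `sweep`, `tpr`, `fpr`) and `auc`.
#' @export
roc_auc <- function(profiles, segmenter, sweep, tolerance_windows = 2) {
  stopifnot(length(sweep) >= 2, length(profiles) >= 1)
  # the negative class (candidate positions 2..N not within tolerance of a
  # true breakpoint) does not depend on the sweep value
  neg <- 0; total_true <- 0
  for (pr in profiles) {
    tb <- pr$truth$breakpoints
    n <- nrow(pr$profile)
    near <- if (length(tb))
      length(unique(unlist(lapply(tb, function(b)
        max(2, b - tolerance_windows):min(n, b + tolerance_windows)))))
    else 0
    neg <- neg + (n - 1) - near
    total_true <- total_true + length(tb)
  }
  pts <- data.frame(sweep = sweep, tpr = NA_real_, fpr = NA_real_)
  for (k in seq_along(sweep)) {
    tp <- 0; fp <- 0
    for (pr in profiles) {
      seg <- segmenter(pr$profile, sweep[k])
      pred <- if (inherits(seg, "slm_segmentation")) seg$breakpoints else seg
      d <- breakpoint_distances(pred, pr$truth$breakpoints)
      tp <- tp + sum(d$truth_to_pred <= tolerance_windows)
      fp <- fp + sum(d$pred_to_truth > tolerance_windows)
    }
    pts$tpr[k] <- if (total_true > 0) tp / total_true else 0
    pts$fpr[k] <- if (neg > 0) fp / neg else 0
  }
  if (nrow(unique(pts[, c("tpr", "fpr")])) == 1)
    warning("all sweep values give the same operating point; ",
            "AUC rests on the (0,0)/(1,1) anchors")
  curve <- rbind(data.frame(fpr = 0, tpr = 0),
                 pts[order(pts$fpr, pts$tpr), c("fpr", "tpr")],
                 data.frame(fpr = 1, tpr = 1))
  curve <- unique(curve)
  auc <- sum(diff(curve$fpr) *
               (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

.size_class <- function(len, breaks) {
  ifelse(len < breaks[1], "SMALL",
         ifelse(len < breaks[2], "MEDIUM", "LARGE"))
}

.overlaps <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  a_chrom == b_chrom & a_start < b_end & a_end > b_start
}

#' Size-stratified precision, recall and F-measure under the any-overlap rule
#'
#' A call counts as a true positive if it overlaps a truth interval by at
#' least one base (and, by default, its copy state matches the truth's
#' direction); otherwise it is a false positive. A truth interval is
#' detected if at least one (matching) call overlaps it. Precision is
#' correctly-detected calls over total calls, recall detected truth
#' intervals over total truth. Results are stratified by truth-interval
#' length into Small (< 20 kb), Medium (>= 20 kb and < 100 kb) and
#' Large (>= 100 kb); false-positive calls are assigned to the class of
#' their own length, matched calls to the class of their best-overlapping
#' truth interval. F-measure is the harmonic mean `2PR / (P + R)` (0 when
#' `P + R = 0`).
#'
#' @param calls Data frame of CNV calls (`chrom`, `start`, `end`,
#'   `copy_state`), e.g. from [call_cnvs()].
#' @param reference Data frame of truth intervals (`chrom`, `start`, `end`
#'   and, for direction matching, `copy_state`), e.g.
#'   `truth$intervals` from the simulator.
#' @param size_breaks Two class boundaries in bp (default 20 kb, 100 kb).
#' @param require_direction Must a TP call's copy state match the truth's?
#'   `FALSE` gives the literal any-overlap rule.
#'
#' @return Data frame with one row per size class plus an `ALL` row:
#'   `class`, `n_truth`, `n_calls`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_measure`. Recall is `NaN` (with a warning) when the
#'   reference is empty; precision is `NaN` for classes with no calls.
#' @export
precision_recall <- function(calls, reference, size_breaks = c(2e4, 1e5),
                             require_direction = TRUE) {
  stopifnot(length(size_breaks) == 2, size_breaks[1] < size_breaks[2])
  if (nrow(reference) == 0)
    warning("empty reference set: recall is undefined (NaN)")
  has_dir <- require_direction && nrow(calls) > 0 && nrow(reference) > 0 &&
    !is.null(calls$copy_state) && !is.null(reference$copy_state)

  ref_class <- .size_class(reference$end - reference$start, size_breaks)
  ref_found <- rep(FALSE, nrow(reference))
  call_tp <- rep(FALSE, max(nrow(calls), 0))
  call_class <- character(nrow(calls))

  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      ov <- which(.overlaps(calls$chrom[i], calls$start[i], calls$end[i],
                            reference$chrom, reference$start, reference$end))
      if (has_dir && length(ov))
        ov <- ov[reference$copy_state[ov] == calls$copy_state[i]]
      if (length(ov)) {
        call_tp[i] <- TRUE
        ref_found[ov] <- TRUE
        span <- pmin(calls$end[i], reference$end[ov]) -
          pmax(calls$start[i], reference$start[ov])
        call_class[i] <- ref_class[ov[which.max(span)]]
      } else {
        call_class[i] <- .size_class(calls$end[i] - calls$start[i],
                                     size_breaks)
      }
    }
  }

  classes <- c("SMALL", "MEDIUM", "LARGE", "ALL")
  out <- do.call(rbind, lapply(classes, function(cl) {
    in_ref <- if (cl == "ALL") rep(TRUE, nrow(reference)) else ref_class == cl
    in_call <- if (cl == "ALL") rep(TRUE, nrow(calls)) else call_class == cl
    tp <- sum(call_tp[in_call])
    fp <- sum(!call_tp[in_call])
    n_truth <- sum(in_ref)
    fn <- sum(in_ref & !ref_found)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
    recall <- if (n_truth > 0) sum(in_ref & ref_found) / n_truth else NaN
    pr_sum <- precision + recall
    f <- if (is.finite(pr_sum) && pr_sum > 0)
      2 * precision * recall / pr_sum else 0
    data.frame(class = cl, n_truth = n_truth, n_calls = sum(in_call),
               tp = tp, fp = fp, fn = fn, precision = precision,
               recall = recall, f_measure = f, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
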