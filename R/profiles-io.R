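#' Construct a genomic profile
#'
#' A genomic profile is an ordered sequence of non-overlapping windows on a
#' single chromosome, each carrying one numeric value: a raw window read
#' count (`scale = "RC"`) or a log2-ratio relative to a diploid reference
#' (`scale = "LOG2RATIO"`). Coordinates are 0-based half-open (BED
#' convention). Windows are sorted by start on construction.
#'
#' @param chrom Chromosome name, length 1 or one per window (all equal).
#' @param start Integer-valued window starts (bp, 0-based inclusive).
#' @param end Integer-valued window ends (bp, exclusive); `end > start`.
#' @param value Numeric signal per window. Must be finite for
#'   `LOG2RATIO`; non-negative and finite for `RC`.
#' @param scale Signal scale, `"LOG2RATIO"` or `"RC"`.
#' @param gc Optional per-window GC fraction in \[0, 1\].
#' @param mappability Optional per-window mappable fraction in \[0, 1\].
#'
#' @return A data frame of class `genomic_profile` with columns
#'   `chrom`, `start`, `end`, `value` (plus `gc`/`mappability` when given)
#'   and a `"scale"` attribute.
#' @export
#' @examples
#' genomic_profile("chr1", c(0, 100), c(100, 200), c(0.1, -0.9))
genomic_profile <- function(chrom, start, end, value,
                            scale = c("LOG2RATIO", "RC"),
                            gc = NULL, mappability = NULL) {
  scale <- match.arg(scale)
  n <- length(start)
  if (n < 1) stop("a genomic profile needs at least one window")
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n || length(value) != n)
    stop("chrom, start, end and value must have equal length")
  if (length(unique(chrom)) != 1)
    stop("all windows of a profile must lie on one chromosome; ",
         "use read_profile() to split multi-chromosome tables")
  bad <- which(!(end > start))
  if (length(bad))
    stop("window end must exceed start (first offending window: ", bad[1], ")")
  if (anyNA(value) || any(!is.finite(value))) {
    if (scale == "LOG2RATIO")
      stop("log2-ratio values must be finite; filter non-finite windows first")
  }
  if (scale == "RC" && any(value < 0, na.rm = TRUE))
    stop("read counts must be non-negative")

  ord <- order(start)
  df <- data.frame(chrom = chrom[ord], start = as.numeric(start[ord]),
                   end = as.numeric(end[ord]), value = value[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(gc)) {
    stopifnot(length(gc) == n, all(gc >= 0 & gc <= 1, na.rm = TRUE))
    df$gc <- gc[ord]
  }
  if (!is.null(mappability)) {
    stopifnot(length(mappability) == n,
              all(mappability >= 0 & mappability <= 1, na.rm = TRUE))
    df$mappability <- mappability[ord]
  }
  ov <- which(df$start[-1] < df$end[-n])
  if (length(ov))
    stop("windows overlap (after sorting, windows ", ov[1], " and ",
         ov[1] + 1, ")")
  structure(df, class = c("genomic_profile", "data.frame"), scale = scale)
}

#' @rdname genomic_profile
#' @param x A `genomic_profile`.
#' @export
profile_scale <- function(x) attr(x, "scale")

#' @export
print.genomic_profile <- function(x, ...) {
  cat(sprintf("genomic_profile: %d windows on %s [%s scale], %g-%g bp\n",
              nrow(x), x$chrom[1], attr(x, "scale"),
              x$start[1], x$end[nrow(x)]))
  NextMethod()
}

# resolve a column-spec entry (index or name) against a table
.resolve_col <- function(tab, spec, role, required = TRUE) {
  if (is.null(spec) || (length(spec) == 1 && is.na(spec))) {
    if (required) stop("column spec is missing required column '", role, "'")
    return(NULL)
  }
  if (is.character(spec)) {
    if (!spec %in% names(tab))
      stop("required column '", role, "' ('", spec, "') not found in file")
    return(tab[[spec]])
  }
  spec <- as.integer(spec)
  if (spec < 1 || spec > ncol(tab))
    stop("required column '", role, "' (index ", spec, ") not found in file")
  tab[[spec]]
}

#' Read genomic profiles from a tab-delimited table
#'
#' Reads a tab-delimited window table (gzip-transparent) and returns one
#' [genomic_profile] per chromosome encountered. Rows may arrive in any
#' order; they are sorted by start within each chromosome. Overlapping
#' windows and windows with `end <= start` are rejected with the offending
#' line number.
#'
#' @param path Path to a tab-delimited file (`.gz` accepted).
#' @param columns Named list/vector mapping roles `chrom`, `start`, `end`,
#'   `value` (required) and `gc`, `mappability` (optional) to column
#'   indices or, when `header = TRUE`, column names.
#' @param header Does the file carry a header line?
#' @param scale Signal scale of the value column (see [genomic_profile]).
#' @param sep Field separator.
#'
#' @return A named list of `genomic_profile` objects, one per chromosome,
#'   in order of first appearance.
#' @export
read_profile <- function(path,
                         columns = c(chrom = 1, start = 2, end = 3, value = 4),
                         header = FALSE,
                         scale = c("LOG2RATIO", "RC"),
                         sep = "\t") {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = header, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty profile table: ", path)
  columns <- as.list(columns)
  chrom <- as.character(.resolve_col(tab, columns$chrom, "chrom"))
  start <- as.numeric(.resolve_col(tab, columns$start, "start"))
  end   <- as.numeric(.resolve_col(tab, columns$end, "end"))
  value <- as.numeric(.resolve_col(tab, columns$value, "value"))
  gc    <- .resolve_col(tab, columns$gc, "gc", required = FALSE)
  mapp  <- .resolve_col(tab, columns$mappability, "mappability",
                        required = FALSE)

  line_of <- function(row) row + as.integer(header)
  bad <- which(!(end > start))
  if (length(bad))
    stop("window end <= start at line ", line_of(bad[1]), " of ", path)

  out <- list()
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    ord <- idx[order(start[idx])]
    ov <- which(start[ord][-1] < end[ord][-length(ord)])
    if (length(ov))
      stop("overlapping windows on ", chr, " at line ",
           line_of(ord[ov[1] + 1]), " of ", path)
    out[[chr]] <- genomic_profile(chr, start[ord], end[ord], value[ord],
                                  scale = scale,
                                  gc = if (!is.null(gc)) as.numeric(gc[ord]),
                                  mappability = if (!is.null(mapp))
                                    as.numeric(mapp[ord]))
  }
  out
}

# full-precision numeric formatting so tables round-trip bit-exactly
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a genomic profile to a tab-delimited table
#'
#' Values are written with 17 significant digits so that
#' `read_profile(write_profile(...))` round-trips finite doubles
#' bit-identically.
#'
#' @param profile A [genomic_profile].
#' @param path Output path; a `.gz` suffix writes gzip.
#' @param header Write a header line?
#' @export
write_profile <- function(profile, path, header = FALSE) {
  stopifnot(inherits(profile, "genomic_profile"))
  cols <- list(profile$chrom, .fmt_num(profile$start), .fmt_num(profile$end),
               .fmt_num(profile$value))
  nm <- c("chrom", "start", "end", "value")
  if (!is.null(profile$gc)) { cols <- c(cols, list(.fmt_num(profile$gc))); nm <- c(nm, "gc") }
  if (!is.null(profile$mappability)) {
    cols <- c(cols, list(.fmt_num(profile$mappability))); nm <- c(nm, "mappability")
  }
  out <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  names(out) <- nm
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

# internal segmentation constructor; checks the partition invariants
new_segmentation <- function(segments, values) {
  n <- length(values)
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "n_windows", "mean_level") %in%
                  names(segments)))
  if (segments$start[1] != 1 || segments$end[nrow(segments)] != n ||
      (nrow(segments) > 1 &&
       any(segments$start[-1] != segments$end[-nrow(segments)] + 1)))
    stop("segments must partition 1..N with no gaps or overlaps")
  if (any(segments$n_windows != segments$end - segments$start + 1))
    stop("segment n_windows inconsistent with boundaries")
  levels <- rep(segments$mean_level, segments$n_windows)
  structure(list(levels = levels,
                 segments = segments,
                 breakpoints = segments$start[-1]),
            class = "slm_segmentation")
}

#' @export
print.slm_segmentation <- function(x, ...) {
  cat(sprintf("slm_segmentation: %d windows, %d segments, %d breakpoints\n",
              length(x$levels), nrow(x$segments), length(x$breakpoints)))
  print(utils::head(x$segments, 10))
  if (nrow(x$segments) > 10) cat("...\n")
  invisible(x)
}

#' Write a segmentation as a tab-delimited segment table
#'
#' One row per segment with columns `chrom`, `start`, `end` (bp, taken from
#' the first window's start and the last window's end of the segment),
#' `n_windows`, `mean_level`. Means are written with 17 significant digits
#' and round-trip exactly.
#'
#' @param seg An `slm_segmentation` produced from `profile`.
#' @param profile The [genomic_profile] that was segmented.
#' @param path Output path.
#' @export
write_segments <- function(seg, profile, path) {
  stopifnot(inherits(seg, "slm_segmentation"),
            inherits(profile, "genomic_profile"))
  if (length(seg$levels) != nrow(profile))
    stop("segmentation length (", length(seg$levels),
         ") does not match profile length (", nrow(profile), ")")
  s <- seg$segments
  out <- data.frame(chrom = profile$chrom[1],
                    start = .fmt_num(profile$start[s$start]),
                    end = .fmt_num(profile$end[s$end]),
                    n_windows = s$n_windows,
                    mean_level = .fmt_num(s$mean_level),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#'
#' @param path Path to a tab-delimited segment table.
#' @return Data frame with columns `chrom`, `start`, `end`, `n_windows`,
#'   `mean_level`.
#' @export
read_segments <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("segment table needs 5 columns")
  names(tab)[1:5] <- c("chrom", "start", "end", "n_windows", "mean_level")
  tab$start <- as.numeric(tab$start); tab$end <- as.numeric(tab$end)
  tab$n_windows <- as.integer(tab$n_windows)
  tab$mean_level <- as.numeric(tab$mean_level)
  tab
}

#' Write CNV calls as a BED-like table
#'
#' Columns: `chrom`, `start`, `end`, `copy_state`, `mean_level`
#' (0-based half-open coordinates).
#'
#' @param calls Data frame of CNV calls (see [call_cnvs()]).
#' @param path Output path.
#' @export
write_cnv_bed <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom,
                    start = .fmt_num(calls$start),
                    end = .fmt_num(calls$end),
                    copy_state = as.character(calls$copy_state),
                    mean_level = .fmt_num(calls$mean_level),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like interval table of CNV calls or truth intervals
#'
#' @param path Path to a tab-delimited file with columns chrom, start, end
#'   and optionally copy_state (4th column).
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present, `copy_state`.
#' @export
read_intervals <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("interval table needs at least 3 columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$copy_state <- as.character(tab[[4]])
  out
}
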