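#' Per-base DNA accessibility tracks
#'
#' An accessibility track is a numeric vector with one value per base, each in
#' \[0, 1\]: the probability that the chromatin at that base is open to TF
#' binding. Binary tracks (0/1) come from thresholded DNase accessibility
#' calls; continuous tracks from read densities via
#' [accessibility_from_read_density()]. A `NULL` accessibility everywhere in
#' this package means naked DNA (a = 1 at every base).
#'
#' @param values numeric vector of per-base accessibilities in \[0, 1\].
#' @param mode `"binary"` or `"continuous"`; checked against the values.
#' @return numeric vector of class `accessibility_track` with attribute `mode`.
#' @export
accessibility_track <- function(values, mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("accessibility values must be finite and in [0, 1]")
  if (mode == "binary" && any(values != 0 & values != 1))
    stop("binary accessibility values must be 0 or 1")
  structure(values, mode = mode, class = "accessibility_track")
}

#' @export
print.accessibility_track <- function(x, ...) {
  cat(sprintf("Accessibility track (%s): %d bp, %.1f%% accessible mass\n",
              attr(x, "mode"), length(x), 100 * mean(unclass(x))))
  invisible(x)
}

#' Binary accessibility from BED-style intervals
#'
#' Bases covered by an interval get a = 1, all others a = 0.
#'
#' @param intervals data frame with columns `start`, `end` (0-based half-open,
#'   the BED convention) and optionally `chrom`; or a `GRanges`.
#' @param seq_length genome/sequence length in bp.
#' @param chrom if `intervals` has a `chrom` column, restrict to this one.
#' @return binary `accessibility_track` of length `seq_length`.
#' @export
accessibility_from_bed <- function(intervals, seq_length, chrom = NULL) {
  if (methods::is(intervals, "GRanges")) {
    intervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(intervals)),
      start = GenomicRanges::start(intervals) - 1L,
      end = GenomicRanges::end(intervals))
  }
  if (!is.null(chrom) && "chrom" %in% names(intervals))
    intervals <- intervals[intervals$chrom == chrom, , drop = FALSE]
  a <- numeric(seq_length)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$end[i] > seq_length || intervals$start[i] < 0)
      stop("interval ", i, " exceeds the sequence length")
    s <- intervals$start[i] + 1L   # BED 0-based -> 1-based
    e <- intervals$end[i]
    if (s <= e) a[s:e] <- 1
  }
  accessibility_track(a, "binary")
}

#' Continuous accessibility from a read-density track
#'
#' Maps a non-negative per-base read density (e.g. DNase-seq coverage) to an
#' accessibility probability in \[0, 1\] with a logistic function of
#' log-density:
#' \deqn{a(d) = 1 / (1 + (d / midpoint)^{-1/scale})}
#' Monotone in `d`, with `a(midpoint) = 0.5` and `a(0) = 0`.
#'
#' @param density non-negative per-base read densities.
#' @param midpoint density mapped to accessibility 0.5; defaults to the median
#'   of the positive densities.
#' @param scale logistic width in log-density units (smaller = sharper).
#' @return continuous `accessibility_track`.
#' @export
accessibility_from_read_density <- function(density, midpoint = NULL,
                                            scale = 1) {
  density <- as.numeric(density)
  if (any(!is.finite(density)) || any(density < 0))
    stop("read densities must be finite and non-negative")
  if (scale <= 0) stop("'scale' must be positive")
  if (is.null(midpoint)) {
    pos <- density[density > 0]
    if (!length(pos)) return(accessibility_track(numeric(length(density)),
                                                 "continuous"))
    midpoint <- stats::median(pos)
  }
  a <- ifelse(density == 0, 0,
              stats::plogis((log(density) - log(midpoint)) / scale))
  accessibility_track(a, "continuous")
}

# window-mean accessibility for every scan window start (length L - m + 1);
# NULL accessibility = naked DNA
.window_accessibility <- function(accessibility, seq_length, motif_length) {
  n_win <- seq_length - motif_length + 1L
  if (is.null(accessibility)) return(rep(1, n_win))
  if (length(accessibility) != seq_length)
    stop("accessibility track length (", length(accessibility),
         ") does not match the sequence length (", seq_length, ")")
  cs <- c(0, cumsum(as.numeric(accessibility)))
  (cs[seq_len(n_win) + motif_length] - cs[seq_len(n_win)]) / motif_length
}

# per-site accessibility for a tfbs_sites table
.site_accessibility <- function(sites, accessibility) {
  L <- attr(sites, "seq_length")
  m <- attr(sites, "motif_length")
  aw <- .window_accessibility(accessibility, L, m)
  aw[sites$start]
}
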