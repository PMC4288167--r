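#' Build a position weight matrix from base counts
#'
#' Converts a 4 x m count matrix (rows A, C, G, T) into a log-odds scoring
#' matrix. A pseudo-count is distributed over the four bases in proportion to
#' the background frequencies before normalising each column, so that zero
#' counts yield finite scores whenever `pseudo_count > 0`.
#'
#' Scores are reported in bits (log2 of the frequency/background ratio). The
#' occupancy model exponentiates them in natural units, i.e. the Boltzmann
#' weight of a site is `(f/b)^(1/lambda)` -- see [genomic_boltzmann_average()].
#'
#' @param counts 4 x m numeric matrix of non-negative base counts; rows in
#'   A, C, G, T order (rownames, if present, are checked).
#' @param pseudo_count non-negative pseudo-count added to each column, split
#'   across bases in proportion to `background`.
#' @param background numeric(4), base background frequencies; must be positive
#'   and sum to 1.
#' @param name motif label.
#' @return An object of class `tf_pwm`: a list with elements `mat` (4 x m
#'   log2-odds scores), `freq` (4 x m frequencies after pseudo-count),
#'   `counts`, `background`, `pseudo_count` and `name`.
#' @examples
#' counts <- matrix(c(4, 0, 0, 0), nrow = 4)
#' pwm <- build_pwm(counts, pseudo_count = 1)
#' pwm$mat["A", 1]  # log2(0.85 / 0.25)
#' @export
build_pwm <- function(counts, pseudo_count = 1, background = rep(0.25, 4),
                      name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("'counts' must have 4 rows (A, C, G, T); got ", nrow(counts))
  if (ncol(counts) < 1L) stop("'counts' must have at least one column")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("'counts' must be finite and non-negative")
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), DNA_BASES))
    stop("count matrix rows must be in A, C, G, T order")
  .check_background(background)
  if (length(pseudo_count) != 1L || !is.finite(pseudo_count) || pseudo_count < 0)
    stop("'pseudo_count' must be a single non-negative number")
  col_tot <- colSums(counts)
  if (pseudo_count == 0 && any(col_tot == 0))
    stop("column with all-zero counts requires pseudo_count > 0")
  freq <- sweep(counts + pseudo_count * background, 2L,
                col_tot + pseudo_count, "/")
  if (pseudo_count == 0 && any(freq == 0))
    stop("zero frequency with pseudo_count = 0 gives an infinite score; ",
         "use pseudo_count > 0")
  mat <- log2(freq / background)
  dimnames(mat) <- dimnames(freq) <- list(DNA_BASES, NULL)
  structure(list(mat = mat, freq = freq, counts = counts,
                 background = background,
                 pseudo_count = pseudo_count, name = name),
            class = "tf_pwm")
}

DNA_BASES <- c("A", "C", "G", "T")

.check_background <- function(background) {
  if (length(background) != 4L || any(!is.finite(background)) ||
      any(background <= 0) || abs(sum(background) - 1) > 1e-9)
    stop("'background' must be 4 positive frequencies summing to 1")
  invisible(background)
}

#' @export
print.tf_pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix '%s': %d positions\n", x$name,
              ncol(x$mat)))
  cat(sprintf("  consensus: %s\n", consensus_sequence(x)))
  cat(sprintf("  information content: %.2f bits\n", information_content(x)))
  cat(sprintf("  score range per site: [%.2f, %.2f] bits\n",
              sum(apply(x$mat, 2L, min)), sum(apply(x$mat, 2L, max))))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a `tf_pwm` object.
#' @return character consensus (highest-frequency base per position).
#' @export
consensus_sequence <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 2L, which.max)], collapse = "")
}

#' Information content of a PWM
#'
#' Total relative entropy (in bits) of the frequency columns against the
#' background: `sum_i sum_b f_bi log2(f_bi / background_b)`. Zero iff every
#' column equals the background.
#'
#' @param pwm a `tf_pwm` object.
#' @return information content in bits.
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "tf_pwm"))
  f <- pwm$freq
  sum(f * log2(f / pwm$background))
}

#' Scan a DNA sequence with a PWM
#'
#' Scores every length-m window on both strands (the minus strand is scored on
#' the reverse complement). Windows containing non-ACGT characters are masked:
#' they are excluded from the returned site table but still counted in the
#' total number of genomic site slots (`attr(sites, "n_slots")`), since masked
#' sequence occupies physical genome length.
#'
#' @param pwm a `tf_pwm` object.
#' @param sequence DNA string (A/C/G/T/N; case-insensitive).
#' @param chrom chromosome/sequence label attached to the result.
#' @param both_strands scan the reverse strand as well (default `TRUE`).
#' @return A `tfbs_sites` data frame with columns `start` (1-based window
#'   start on the forward strand), `strand` and `score` (bits), ordered by
#'   start then strand. Attributes: `chrom`, `motif_length`, `seq_length`,
#'   `n_slots` (scanned window slots per genome copy, masked ones included)
#'   and `score_range` (over retained windows).
#' @export
score_sequence <- function(pwm, sequence, chrom = "chr1", both_strands = TRUE) {
  stopifnot(inherits(pwm, "tf_pwm"))
  codes <- encode_dna(sequence)
  m <- ncol(pwm$mat)
  L <- length(codes)
  if (L < m)
    stop("sequence length (", L, ") is shorter than the motif (", m, ")")
  n_win <- L - m + 1L
  fwd <- .scan_codes(codes, pwm$mat)
  starts <- seq_len(n_win)
  if (both_strands) {
    # minus-strand score at start i == forward scan with the
    # reverse-complemented matrix
    rc_mat <- pwm$mat[4:1, rev(seq_len(m)), drop = FALSE]
    rev_sc <- .scan_codes(codes, rc_mat)
    sites <- data.frame(
      start = c(starts, starts),
      strand = rep(c("+", "-"), each = n_win),
      score = c(fwd, rev_sc))
  } else {
    sites <- data.frame(start = starts, strand = "+", score = fwd)
  }
  keep <- !is.na(sites$score)
  sites <- sites[keep, , drop = FALSE]
  ord <- order(sites$start, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  n_slots <- if (both_strands) 2L * n_win else n_win
  structure(sites,
            chrom = chrom, motif_length = m, seq_length = L,
            n_slots = n_slots,
            score_range = if (nrow(sites)) range(sites$score) else c(NA_real_, NA_real_),
            class = c("tfbs_sites", "data.frame"))
}

#' @keywords internal
.scan_codes <- function(codes, mat) {
  m <- ncol(mat)
  n_win <- length(codes) - m + 1L
  sc <- numeric(n_win)
  for (k in seq_len(m)) {
    sc <- sc + mat[, k][codes[k:(k + n_win - 1L)]]
  }
  sc
}

#' Encode a DNA string as integer base codes
#'
#' A=1, C=2, G=3, T=4; anything else (N, gaps) becomes `NA`.
#' @param sequence DNA string.
#' @return integer vector of base codes.
#' @keywords internal
encode_dna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  raw <- charToRaw(toupper(sequence))
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 1:4
  lut[as.integer(raw) + 1L]
}

decode_dna <- function(codes) {
  paste(c(DNA_BASES, "N")[replace(codes, is.na(codes), 5L)], collapse = "")
}

#' Filter scored sites by relative PWM score
#'
#' Retains the sites whose score passes a threshold defined as a fraction of
#' the score range observed over the scanned region. Two modes:
#' \describe{
#'   \item{`offset_from_min`}{threshold = `min + fraction * (max - min)`
#'     (default). A fraction of 0.7 keeps the top 30 percent of the score
#'     *range*.}
#'   \item{`absolute_range`}{threshold = `fraction * (max - min)`, the score
#'     range itself used as an absolute cut-off. With strongly negative
#'     minimum scores this threshold can exceed the maximum score and select
#'     nothing; it is provided for comparability.}
#' }
#' The range is the one recorded when the region was scanned
#' (`attr(sites, "score_range")`), so the filter is idempotent.
#'
#' @param sites a `tfbs_sites` object from [score_sequence()].
#' @param fraction numeric in \[0, 1\].
#' @param mode `"offset_from_min"` or `"absolute_range"`.
#' @return filtered `tfbs_sites`; attributes are preserved and
#'   `threshold_fraction`, `threshold_mode`, `threshold` are recorded.
#' @export
filter_by_relative_score <- function(sites, fraction = 0.7,
                                     mode = c("offset_from_min",
                                              "absolute_range")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sites, "tfbs_sites"))
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be a single number in [0, 1]")
  if (nrow(sites) == 0L) {
    warning("no sites to filter; returning empty site set")
    return(sites)
  }
  rng <- attr(sites, "score_range")
  thr <- switch(mode,
    offset_from_min = rng[1] + fraction * (rng[2] - rng[1]),
    absolute_range = fraction * (rng[2] - rng[1]))
  out <- sites[sites$score >= thr, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("chrom", "motif_length", "seq_length", "n_slots", "score_range"))
    attr(out, a) <- attr(sites, a)
  attr(out, "threshold_fraction") <- fraction
  attr(out, "threshold_mode") <- mode
  attr(out, "threshold") <- thr
  class(out) <- c("tfbs_sites", "data.frame")
  out
}

#' Reverse complement of a DNA string
#' @param sequence DNA string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
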