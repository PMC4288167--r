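#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a JASPAR-style PWM count matrix
#'
#' Accepts the common 4-row text layouts: an optional `>name` header,
#' rows either bare whitespace-separated numbers or the
#' `A  [ 1 2 3 ]` bracketed style, in A, C, G, T order.
#'
#' @param path motif file.
#' @param pseudo_count,background passed to [build_pwm()].
#' @return a `tf_pwm`.
#' @export
read_pwm <- function(path, pseudo_count = 1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- "motif"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4L)
    stop("PWM file must contain 4 rows of counts (A, C, G, T)")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("[][]", " ", l)
    l <- sub("^\\s*[ACGTacgt]\\s+", " ", paste0(" ", l))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(vals)))
      stop("malformed PWM row: '", lines[which(lines == lines[1])], "'")
    vals
  })
  len <- unique(lengths(rows))
  if (length(len) != 1L)
    stop("PWM rows have unequal lengths: ",
         paste(lengths(rows), collapse = ", "))
  counts <- do.call(rbind, rows)
  rownames(counts) <- DNA_BASES
  build_pwm(counts, pseudo_count = pseudo_count, background = background,
            name = name)
}

#' Write a PWM count matrix in JASPAR-style text
#'
#' Writes the original counts stored in the `tf_pwm` (falling back to the
#' frequency matrix rescaled to 100) or a plain 4 x m count matrix.
#'
#' @param pwm a `tf_pwm` or a plain 4 x m count matrix.
#' @param path output file.
#' @param counts optional explicit count matrix to write instead.
#' @export
write_pwm <- function(pwm, path, counts = NULL) {
  if (is.null(counts)) {
    counts <- if (!inherits(pwm, "tf_pwm")) pwm
              else if (!is.null(pwm$counts)) pwm$counts
              else round(pwm$freq * 100)
  }
  name <- if (inherits(pwm, "tf_pwm")) pwm$name else "motif"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (i in 1:4)
    writeLines(paste(c(DNA_BASES[i], counts[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read BED intervals
#'
#' @param path BED file.
#' @return data frame with `chrom`, `start`, `end` (0-based half-open, as in
#'   the file).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Read a bedGraph or wiggle track as a per-base vector
#'
#' Uses the declared format (by file extension: `.wig` = wiggle, otherwise
#' bedGraph). Positions not covered by any interval get 0.
#'
#' @param path track file.
#' @param seq_length output length; defaults to the last covered position.
#'   An interval beyond `seq_length` is an error.
#' @param chrom restrict to one chromosome (default: first seen).
#' @return numeric per-base vector.
#' @export
read_track <- function(path, seq_length = NULL, chrom = NULL) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(chrom)) chrom <- chroms[1]
  gr <- gr[chroms == chrom]
  if (!length(gr)) stop("no intervals for ", chrom, " in ", path)
  ends <- GenomicRanges::end(gr)
  if (is.null(seq_length)) seq_length <- max(ends)
  if (max(ends) > seq_length)
    stop("track extends to ", max(ends), " bp, beyond the sequence length (",
         seq_length, " bp)")
  v <- numeric(seq_length)
  starts <- GenomicRanges::start(gr)
  score <- gr$score
  for (i in seq_along(starts)) v[starts[i]:ends[i]] <- score[i]
  v
}

#' Write a per-base track as bedGraph
#'
#' Consecutive equal values are run-length collapsed; zero runs are omitted.
#' Values are written with full precision so a write/read round trip is
#' exact.
#'
#' @param track numeric per-base vector.
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_bedgraph <- function(track, path, chrom = "chr1") {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values != 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, starts[keep], ends[keep],
                     r$values[keep]), con)
  invisible(path)
}

#' Write a per-base track as fixedStep wiggle
#'
#' @param track numeric per-base vector.
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_wig <- function(track, path, chrom = "chr1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
  writeLines(sprintf("%.17g", track), con)
  invisible(path)
}

# boolean per-base vector -> BED intervals of TRUE runs
write_bed_from_track <- function(flag, chrom, path) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d", chrom, starts[keep], ends[keep]), con)
  invisible(path)
}

#' Package configuration
#'
#' `default_config()` returns every tunable with its default;
#' `load_config(path)` reads a YAML file and merges it over the defaults,
#' rejecting unknown keys by name.
#'
#' @return named list of settings.
#' @export
default_config <- function() {
  list(pseudo_count = 1, ploidy = 2L, threshold = 0.7,
       threshold_mode = "offset_from_min",
       fragment_mean = 200, fragment_sd = 200, smooth_window = 250,
       bin = 1000, normalization = "none", metric_domain = "accessible",
       noise_model = "censored", band_fraction = 0.12,
       region_size = 20000, background_mult = 1,
       N_grid = default_N_grid(), lambda_grid = default_lambda_grid(),
       seed = 42L, log_level = "info")
}

#' @rdname default_config
#' @param path YAML configuration file.
#' @export
load_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' @rdname default_config
#' @param config configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
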