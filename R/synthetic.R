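#' Specification of a synthetic occupancy benchmark
#'
#' Collects every tunable of the synthetic-data generator, with defaults
#' describing the standard benchmark: a 200-kb random genome carrying 50
#' planted motif instances, block-structured binary accessibility covering
#' 15% of the genome, and a forward-simulated observed profile at N = 5000
#' bound molecules and specificity lambda = 1.5 with additive noise at 10%
#' of the profile peak.
#'
#' @param genome_length genome length, bp.
#' @param gc_content GC fraction of the random background.
#' @param n_planted_sites number of motif instances written into the genome.
#' @param site_strength_range quantile window (of the PWM's own sampled-word
#'   score distribution) from which planted site strengths are drawn.
#' @param accessible_fraction fraction of the genome that is accessible.
#' @param accessible_segment_mean mean accessible block length, bp.
#' @param true_N,true_lambda parameters of the forward simulation.
#' @param noise_sd observation noise, as a fraction of the noiseless profile
#'   maximum.
#' @param ploidy genome copies per nucleus.
#' @param sites_in_accessible force planted sites into accessible blocks
#'   (needed for parameter-recovery benchmarks: sites in closed chromatin are
#'   invisible to the model by construction).
#' @param min_spacing minimum distance between planted site starts, bp.
#' @param threshold,threshold_mode relative-score filter used when forward-
#'   simulating the observed profile.
#' @param fragment_mean,fragment_sd,smooth_window profile parameters.
#' @param seed integer seed fixing all randomness of the fixture.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 200000, gc_content = 0.5,
                           n_planted_sites = 50,
                           site_strength_range = c(0.3, 1),
                           accessible_fraction = 0.15,
                           accessible_segment_mean = 1000,
                           true_N = 5000, true_lambda = 1.5,
                           noise_sd = 0.1, ploidy = 2L,
                           sites_in_accessible = FALSE,
                           min_spacing = 100,
                           threshold = 0.7,
                           threshold_mode = "offset_from_min",
                           fragment_mean = 200, fragment_sd = 200,
                           smooth_window = 250, seed = 42L) {
  spec <- list(genome_length = genome_length, gc_content = gc_content,
               n_planted_sites = n_planted_sites,
               site_strength_range = site_strength_range,
               accessible_fraction = accessible_fraction,
               accessible_segment_mean = accessible_segment_mean,
               true_N = true_N, true_lambda = true_lambda,
               noise_sd = noise_sd, ploidy = as.integer(ploidy),
               sites_in_accessible = sites_in_accessible,
               min_spacing = min_spacing,
               threshold = threshold, threshold_mode = threshold_mode,
               fragment_mean = fragment_mean, fragment_sd = fragment_sd,
               smooth_window = smooth_window, seed = as.integer(seed))
  stopifnot(genome_length > 0, gc_content >= 0, gc_content <= 1,
            n_planted_sites >= 0,
            length(site_strength_range) == 2L,
            all(site_strength_range >= 0), all(site_strength_range <= 1),
            site_strength_range[1] <= site_strength_range[2],
            accessible_fraction >= 0, accessible_fraction <= 1,
            accessible_segment_mean > 0, true_N > 0, true_lambda > 0,
            noise_sd >= 0)
  structure(spec, class = "synthetic_spec")
}

#' Default synthetic motif
#'
#' A 10-bp moderate-information motif (IC about 5.8 bits) used by the
#' synthetic benchmark: each column has one dominant base at count 14 of 20
#' (two sharper anchor columns at 17 of 20). A moderate motif keeps the
#' genomic partition function dominated by the many background windows rather
#' than by the few planted sites, which is the regime the analytical
#' occupancy model assumes for genome-scale data.
#'
#' @param pseudo_count pseudo-count for [build_pwm()].
#' @return a `tf_pwm`.
#' @export
default_pwm <- function(pseudo_count = 1) {
  build_pwm(default_pwm_counts(), pseudo_count = pseudo_count, name = "SYN10")
}

#' @rdname default_pwm
#' @export
default_pwm_counts <- function() {
  consensus <- c(4L, 3L, 1L, 2L, 3L, 4L, 2L, 1L, 3L, 1L)  # TGACGTCATG -> idx
  counts <- matrix(2L, 4L, 10L, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(10L)) counts[consensus[i], i] <- 14L
  counts
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at the requested GC content (G and C equally likely, likewise
#' A and T).
#'
#' @param length genome length, bp.
#' @param gc_content GC fraction.
#' @return DNA string.
#' @export
generate_genome <- function(length, gc_content = 0.5) {
  if (length <= 0) stop("'length' must be positive")
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a block-structured binary accessibility track
#'
#' Alternating accessible/inaccessible blocks with geometrically distributed
#' lengths; accessible blocks have the requested mean length and the gaps are
#' scaled so the expected accessible fraction is met.
#'
#' @param length track length, bp.
#' @param accessible_fraction expected accessible fraction.
#' @param segment_mean mean accessible block length, bp.
#' @return binary `accessibility_track`.
#' @export
generate_accessibility <- function(length, accessible_fraction = 0.15,
                                   segment_mean = 1000) {
  if (accessible_fraction >= 1)
    return(accessibility_track(rep(1, length), "binary"))
  if (accessible_fraction <= 0)
    return(accessibility_track(numeric(length), "binary"))
  gap_mean <- segment_mean * (1 - accessible_fraction) / accessible_fraction
  a <- numeric(length)
  pos <- 1L
  open <- stats::runif(1) < accessible_fraction
  while (pos <= length) {
    mean_len <- if (open) segment_mean else gap_mean
    len <- stats::rgeom(1, 1 / mean_len) + 1L
    if (open) a[pos:min(length, pos + len - 1L)] <- 1
    pos <- pos + len
    open <- !open
  }
  accessibility_track(a, "binary")
}

#' Plant motif instances into a genome
#'
#' Writes sampled motif words (columns drawn from the PWM frequencies,
#' restricted to a strength quantile window of the sampled-word score
#' distribution) at non-overlapping positions on random strands. The genome
#' with sites planted and a truth table are returned.
#'
#' @param genome DNA string.
#' @param pwm a `tf_pwm`.
#' @param n_sites number of instances to plant.
#' @param strength_range quantile window of sampled-word scores, e.g.
#'   `c(0.9, 1)` for near-consensus sites.
#' @param min_spacing minimum distance between planted starts, bp.
#' @param positions_allowed optional vector of permitted start positions
#'   (1-based); defaults to the whole genome.
#' @param n_candidates number of candidate words sampled to estimate the
#'   strength quantiles.
#' @return list with `genome` (modified string) and `truth` (data frame:
#'   `start`, `strand`, `word`, `score`).
#' @export
plant_sites <- function(genome, pwm, n_sites, strength_range = c(0.3, 1),
                        min_spacing = 100, positions_allowed = NULL,
                        n_candidates = 500L) {
  m <- ncol(pwm$mat)
  L <- nchar(genome)
  if (n_sites == 0L)
    return(list(genome = genome,
                truth = data.frame(start = integer(), strand = character(),
                                   word = character(), score = numeric())))
  if (n_sites * (m + min_spacing) > L)
    stop("cannot pack ", n_sites, " sites of ", m, " bp with spacing ",
         min_spacing, " into ", L, " bp")
  # candidate words from the PWM's own frequency model, then keep the
  # requested strength quantile window
  words <- vapply(seq_len(n_candidates), function(i)
    vapply(seq_len(m), function(k)
      sample.int(4L, 1L, prob = pwm$freq[, k]), integer(1)),
    integer(m))
  scores <- vapply(seq_len(n_candidates), function(i)
    sum(pwm$mat[cbind(words[, i], seq_len(m))]), numeric(1))
  qs <- stats::quantile(scores, strength_range)
  pool <- which(scores >= qs[1] & scores <= qs[2])
  if (!length(pool)) pool <- which.max(scores)
  allowed <- positions_allowed %||% seq_len(L - m + 1L)
  allowed <- allowed[allowed >= 1L & allowed <= L - m + 1L]
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n_sites) {
    tries <- tries + 1L
    if (tries > 200L * n_sites)
      stop("could not place ", n_sites, " non-overlapping sites; ",
           "relax 'min_spacing' or enlarge the allowed region")
    cand <- allowed[sample.int(length(allowed), 1L)]
    if (!length(starts) || all(abs(starts - cand) >= m + min_spacing))
      starts <- c(starts, cand)
  }
  starts <- sort(starts)
  chosen <- pool[sample.int(length(pool), n_sites, replace = TRUE)]
  strands <- sample(c("+", "-"), n_sites, replace = TRUE)
  gseq <- strsplit(genome, "")[[1]]
  truth <- data.frame(start = starts, strand = strands,
                      word = character(n_sites), score = numeric(n_sites))
  for (i in seq_len(n_sites)) {
    word <- decode_dna(words[, chosen[i]])
    truth$word[i] <- word
    truth$score[i] <- scores[chosen[i]]
    inserted <- if (strands[i] == "+") word else reverse_complement(word)
    gseq[starts[i]:(starts[i] + m - 1L)] <- strsplit(inserted, "")[[1]]
  }
  list(genome = paste(gseq, collapse = ""), truth = truth)
}

#' Build a complete synthetic benchmark fixture
#'
#' Composes the generators: random genome, accessibility track, planted
#' sites, and the forward-simulated noiseless and noisy observed profiles at
#' the spec's true parameters. All randomness derives from `spec$seed`, so a
#' fixture is reproduced exactly from its spec. If `dir` is given, the
#' fixture is also written to standard-format files (FASTA genome,
#' JASPAR-style PWM, BED accessibility, bedGraph observed profile and a JSON
#' truth record).
#'
#' @param spec a [synthetic_spec()].
#' @param pwm motif used for planting and scanning; default [default_pwm()].
#' @param dir optional output directory.
#' @return list of class `synthetic_fixture`: `genome`, `accessibility`,
#'   `pwm`, `truth`, `model` (the precomputed [occupancy_model()]),
#'   `profile` (noiseless), `observed` (noisy), `noise_sd_abs`, `spec` and,
#'   when written, `files`.
#' @export
make_fixture <- function(spec = synthetic_spec(), pwm = default_pwm(),
                         dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  genome <- generate_genome(spec$genome_length, spec$gc_content)
  acc <- generate_accessibility(spec$genome_length,
                                spec$accessible_fraction,
                                spec$accessible_segment_mean)
  m <- ncol(pwm$mat)
  allowed <- if (spec$sites_in_accessible) {
    pos <- which(as.numeric(acc) == 1)
    pos[pos <= spec$genome_length - m + 1L]
  } else NULL
  planted <- plant_sites(genome, pwm, spec$n_planted_sites,
                         strength_range = spec$site_strength_range,
                         min_spacing = spec$min_spacing,
                         positions_allowed = allowed)
  model <- occupancy_model(planted$genome, pwm, acc,
                           threshold = spec$threshold,
                           threshold_mode = spec$threshold_mode,
                           ploidy = spec$ploidy)
  profile <- predict_chip_profile(model, spec$true_N, spec$true_lambda,
                                  fragment_mean = spec$fragment_mean,
                                  fragment_sd = spec$fragment_sd,
                                  smooth_window = spec$smooth_window)
  noise_abs <- spec$noise_sd * max(profile)
  observed <- add_truncated_noise(profile, noise_abs)
  fx <- structure(list(genome = planted$genome, accessibility = acc,
                       pwm = pwm, truth = planted$truth, model = model,
                       profile = profile, observed = observed,
                       noise_sd_abs = noise_abs, spec = spec),
                  class = "synthetic_fixture")
  if (!is.null(dir)) fx$files <- write_fixture(fx, dir)
  fx
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat(sprintf(paste0("Synthetic occupancy fixture: %d bp genome, %d planted",
                     " sites,\n  %.1f%% accessible, true N = %s, true lambda",
                     " = %.2f, noise sd = %.3g (seed %d)\n"),
              x$spec$genome_length, nrow(x$truth),
              100 * mean(as.numeric(x$accessibility)),
              format(x$spec$true_N, big.mark = ","), x$spec$true_lambda,
              x$noise_sd_abs, x$spec$seed))
  invisible(x)
}

#' Write a fixture to standard-format files
#'
#' @param fx a `synthetic_fixture`.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             pwm = file.path(dir, "motif.pwm"),
             accessibility = file.path(dir, "accessibility.bed"),
             observed = file.path(dir, "observed.bedGraph"),
             truth = file.path(dir, "truth.json"))
  write_fasta(stats::setNames(fx$genome, fx$model$chrom), paths["genome"])
  write_pwm(fx$pwm, paths["pwm"])
  write_bed_from_track(as.numeric(fx$accessibility) > 0, fx$model$chrom,
                       paths["accessibility"])
  write_bedgraph(fx$observed, paths["observed"], chrom = fx$model$chrom)
  truth <- list(spec = unclass(fx$spec), sites = fx$truth,
                noise_sd_abs = fx$noise_sd_abs)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  paths
}
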