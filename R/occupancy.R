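#' Boltzmann weight of PWM scores
#'
#' The statistical weight of a site with score `w` bits at specificity
#' `lambda` is the likelihood ratio raised to `1/lambda`:
#' `(f/b)^(1/lambda) = exp(w * ln 2 / lambda)`. Expressed this way the weight
#' does not depend on the base the score matrix is printed in; `lambda` is a
#' dimensionless scaling of the binding energy (in units of kT).
#'
#' @param score PWM score(s) in bits.
#' @param lambda positive specificity scaling factor.
#' @return numeric weights.
#' @export
boltzmann_weight <- function(score, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive number")
  exp(score * log(2) / lambda)
}

#' Genomic average Boltzmann weight
#'
#' The competition term of the occupancy model: the arithmetic mean of
#' `a_i * weight(w_i)` over all genomic site slots of one genome copy. Masked
#' windows (absent from `sites` but counted in `n_slots`) contribute zero
#' weight but still occupy slots.
#'
#' @param sites a `tfbs_sites` table covering every scorable window
#'   (unfiltered).
#' @param accessibility per-base accessibility track, or `NULL` for naked DNA.
#' @param lambda positive specificity factor.
#' @param n_slots total number of site slots; defaults to
#'   `attr(sites, "n_slots")` (both strands, masked windows included) or, for
#'   plain site tables without that attribute, the number of rows.
#' @param site_accessibility optional precomputed per-site accessibilities
#'   (same order as `sites`); overrides `accessibility`.
#' @return the mean weight (strictly positive).
#' @export
genomic_boltzmann_average <- function(sites, accessibility = NULL, lambda,
                                      n_slots = NULL,
                                      site_accessibility = NULL) {
  if (is.null(n_slots)) {
    n_slots <- attr(sites, "n_slots")
    if (is.null(n_slots)) n_slots <- nrow(sites)
  }
  a <- if (!is.null(site_accessibility)) site_accessibility
       else if (inherits(sites, "tfbs_sites") && !is.null(accessibility))
         .site_accessibility(sites, accessibility)
       else if (is.null(accessibility)) rep(1, nrow(sites))
       else as.numeric(accessibility)
  if (length(a) != nrow(sites))
    stop("accessibility does not match the site table")
  tot <- sum(a * boltzmann_weight(sites$score, lambda))
  if (tot <= 0)
    stop("all sites are inaccessible (or zero-weighted): ",
         "the occupancy model is undefined")
  tot / n_slots
}

#' Occupancy probability of a binding site
#'
#' The analytical binding probability of the statistical-thermodynamics
#' model:
#' \deqn{P_j = \frac{N a_j e^{w_j \ln 2/\lambda}}
#'   {N a_j e^{w_j \ln 2/\lambda} + L n \langle a_i e^{w_i \ln 2/\lambda}\rangle_i}}
#' where `N` is the number of DNA-bound molecules, `a_j` the site
#' accessibility, `w_j` the PWM score (bits), `L n` the total number of site
#' slots across `n` genome copies and the angle bracket the genomic average
#' weight ([genomic_boltzmann_average()]).
#'
#' @param score site score(s), bits.
#' @param accessibility site accessibility value(s) in \[0, 1\].
#' @param N number of DNA-bound molecules (positive; real-valued, since it is
#'   an ensemble average over nuclei).
#' @param lambda positive specificity factor.
#' @param avg genomic average weight, from [genomic_boltzmann_average()]
#'   computed at the same `lambda` and accessibility.
#' @param n_slots number of site slots per genome copy.
#' @param ploidy number of genome copies per nucleus (default 2, diploid).
#' @return binding probabilities in \[0, 1\].
#' @export
occupancy_probability <- function(score, accessibility, N, lambda, avg,
                                  n_slots, ploidy = 2L) {
  if (length(N) != 1L || !is.finite(N) || N <= 0)
    stop("'N' must be a single positive number")
  if (ploidy < 1) stop("'ploidy' must be >= 1")
  num <- N * accessibility * boltzmann_weight(score, lambda)
  num / (num + n_slots * ploidy * avg)
}

#' Predict occupancy for a set of reported sites
#'
#' Evaluates the occupancy probability for every site in `filtered_sites`.
#' The genomic average in the denominator is computed over *all* scorable
#' windows (`all_sites`), not only the reported ones: the score filter selects
#' which sites are reported, while the partition-function normalisation is a
#' property of the whole genome.
#'
#' @param filtered_sites `tfbs_sites` to report (typically from
#'   [filter_by_relative_score()]).
#' @param all_sites unfiltered `tfbs_sites` over the same region.
#' @param accessibility per-base accessibility or `NULL` (naked DNA).
#' @param N,lambda model parameters.
#' @param ploidy genome copies per nucleus.
#' @param avg optional precomputed genomic average weight.
#' @return a `site_occupancy` data frame: the filtered sites plus columns
#'   `accessibility` and `probability`.
#' @export
predict_site_occupancy <- function(filtered_sites, all_sites,
                                   accessibility = NULL, N, lambda,
                                   ploidy = 2L, avg = NULL) {
  stopifnot(inherits(filtered_sites, "tfbs_sites"),
            inherits(all_sites, "tfbs_sites"))
  rng <- attr(all_sites, "score_range")
  if (nrow(filtered_sites) &&
      (max(filtered_sites$score) > rng[2] + 1e-9 ||
       min(filtered_sites$score) < rng[1] - 1e-9))
    stop("'filtered_sites' scores fall outside the range of 'all_sites'; ",
         "the filtered set must come from the same scan")
  if (is.null(avg))
    avg <- genomic_boltzmann_average(all_sites, accessibility, lambda)
  n_slots <- attr(all_sites, "n_slots")
  a <- .site_accessibility(filtered_sites, accessibility)
  p <- occupancy_probability(filtered_sites$score, a, N, lambda, avg,
                             n_slots, ploidy)
  out <- as.data.frame(filtered_sites)
  out$accessibility <- a
  out$probability <- p
  structure(out,
            chrom = attr(filtered_sites, "chrom"),
            motif_length = attr(filtered_sites, "motif_length"),
            seq_length = attr(filtered_sites, "seq_length"),
            N = N, lambda = lambda, ploidy = ploidy, avg = avg,
            class = c("site_occupancy", "data.frame"))
}
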