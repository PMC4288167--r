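#' Expected-coverage kernel for ChIP fragments
#'
#' In a ChIP experiment a bound site is recovered on sheared DNA fragments;
#' the expected per-base coverage around a bound position is the mixture, over
#' fragment lengths, of the probability that a random fragment covering the
#' site also covers a base at distance d. Fragment lengths are drawn from a
#' normal distribution truncated at 1 bp and discretised to integers; a
#' fragment of length l is placed uniformly among the l placements that cover
#' the bound position, so its contribution at distance d is
#' `max(0, l - |d|) / l` (a triangular kernel). The closed-form kernel sums
#' these triangles; its total mass equals the mean fragment length exactly.
#'
#' @param fragment_mean mean fragment length, bp.
#' @param fragment_sd fragment length standard deviation, bp; 0 gives a single
#'   deterministic length.
#' @param max_length truncation of the length distribution; defaults to
#'   `fragment_mean + 6 * fragment_sd`.
#' @return object of class `fragment_kernel`: list with `kernel` (coverage
#'   probability at offsets `-(max_length-1) .. (max_length-1)`), `half`
#'   (max offset), `lengths`, `length_prob` and `expected_length`.
#' @export
fragment_kernel <- function(fragment_mean = 200, fragment_sd = 200,
                            max_length = NULL) {
  if (fragment_mean <= 0) stop("'fragment_mean' must be positive")
  if (fragment_sd < 0) stop("'fragment_sd' must be non-negative")
  if (is.null(max_length))
    max_length <- max(1L, ceiling(fragment_mean + 6 * fragment_sd))
  lens <- seq_len(max_length)
  if (fragment_sd == 0) {
    p <- as.numeric(lens == round(fragment_mean))
    if (sum(p) == 0) stop("'fragment_mean' outside truncation range")
  } else {
    p <- stats::dnorm(lens, fragment_mean, fragment_sd)
  }
  p <- p / sum(p)
  half <- max_length - 1L
  d <- abs(seq.int(-half, half))
  # K(d) = sum_l p_l * max(0, l - d) / l, vectorised over offsets via the
  # tail sums of p and p/l
  tail_p <- rev(cumsum(rev(p)))          # P(l > d) terms: sum_{l >= d+1} p_l
  tail_pl <- rev(cumsum(rev(p / lens)))  # sum_{l >= d+1} p_l / l
  Kpos <- function(dd) {
    i <- dd + 1L
    out <- numeric(length(dd))
    ok <- i <= max_length
    out[ok] <- tail_p[i[ok]] - dd[ok] * tail_pl[i[ok]]
    out
  }
  K <- Kpos(d)
  structure(list(kernel = K, half = half, lengths = lens, length_prob = p,
                 expected_length = sum(p * lens),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd),
            class = "fragment_kernel")
}

#' @export
print.fragment_kernel <- function(x, ...) {
  cat(sprintf(paste0("ChIP fragment kernel: mean %.0f bp, sd %.0f bp, ",
                     "support +/- %d bp, mass %.2f\n"),
              x$fragment_mean, x$fragment_sd, x$half, sum(x$kernel)))
  invisible(x)
}

#' Monte-Carlo estimate of the fragment coverage kernel
#'
#' Samples fragments (length from the discretised truncated normal, placement
#' uniform among placements covering the site) and accumulates coverage; used
#' as an independent cross-check of the closed-form kernel.
#'
#' @param fk a `fragment_kernel`.
#' @param n_draws number of fragments to sample.
#' @return list with `kernel` (mean coverage per offset over draws) and
#'   `se` (per-offset standard error).
#' @export
sample_fragment_kernel <- function(fk, n_draws = 1e5) {
  stopifnot(inherits(fk, "fragment_kernel"))
  half <- fk$half
  width <- 2L * half + 1L
  cov_sum <- numeric(width)
  cov_sq <- numeric(width)
  lens <- sample(fk$lengths, n_draws, replace = TRUE, prob = fk$length_prob)
  offs <- floor(stats::runif(n_draws) * lens)  # site offset within fragment
  starts <- -offs                              # fragment start rel. to site
  for (i in seq_len(n_draws)) {
    lo <- starts[i] + half + 1L
    hi <- lo + lens[i] - 1L
    cov_sum[lo:hi] <- cov_sum[lo:hi] + 1
    cov_sq[lo:hi] <- cov_sq[lo:hi] + 1
  }
  mean_cov <- cov_sum / n_draws
  se <- sqrt(pmax(0, cov_sq / n_draws - mean_cov^2) / n_draws)
  list(kernel = mean_cov, se = se)
}

#' Extend site occupancies to a per-base coverage profile
#'
#' Each bound site contributes `P_j` times the expected fragment-coverage
#' kernel centred on the site. Coverage is truncated at the ends of the
#' region; away from the edges the total signal mass equals
#' `sum(P_j) * E[fragment length]`.
#'
#' @param positions site centre positions (1-based).
#' @param probabilities per-site occupancy probabilities.
#' @param seq_length region length, bp.
#' @param kernel a `fragment_kernel`, or `NULL` to build one from
#'   `fragment_mean`/`fragment_sd`.
#' @param fragment_mean,fragment_sd kernel parameters when `kernel` is `NULL`.
#' @return numeric per-base coverage of length `seq_length`.
#' @export
extend_occupancy_to_coverage <- function(positions, probabilities, seq_length,
                                         kernel = NULL, fragment_mean = 200,
                                         fragment_sd = 200) {
  if (length(positions) != length(probabilities))
    stop("'positions' and 'probabilities' lengths differ")
  if (is.null(kernel)) kernel <- fragment_kernel(fragment_mean, fragment_sd)
  stopifnot(inherits(kernel, "fragment_kernel"))
  cov <- numeric(seq_length)
  if (!length(positions)) {
    warning("no sites: returning an all-zero profile")
    return(cov)
  }
  K <- kernel$kernel
  half <- kernel$half
  for (i in which(probabilities > 0)) {
    c0 <- positions[i]
    lo <- max(1L, c0 - half)
    hi <- min(seq_length, c0 + half)
    if (lo > hi) next
    idx <- (lo - c0 + half + 1L):(hi - c0 + half + 1L)
    cov[lo:hi] <- cov[lo:hi] + probabilities[i] * K[idx]
  }
  cov
}

#' Smooth a profile with a centred moving average
#'
#' Window edges shrink near the region boundaries (the average is taken over
#' the bases actually available), so a constant profile is a fixed point and
#' no negative values are ever produced.
#'
#' @param profile numeric per-base signal.
#' @param window smoothing window, bp. An even window is centred with one
#'   more base on the right.
#' @return smoothed profile, same length.
#' @export
smooth_profile <- function(profile, window = 250) {
  if (window < 1) stop("'window' must be >= 1")
  L <- length(profile)
  if (window >= L) return(rep(mean(profile), L))
  hl <- floor((window - 1) / 2)
  hr <- window - 1 - hl
  cs <- c(0, cumsum(profile))
  i <- seq_len(L)
  lo <- pmax(1L, i - hl)
  hi <- pmin(L, i + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Forward-simulate a ChIP-seq-like profile
#'
#' Composition of the full generative pipeline: occupancy probabilities from
#' the analytical model, fragment-kernel extension, moving-average smoothing
#' and optional additive Gaussian noise truncated at zero.
#'
#' @param filtered_sites,all_sites,accessibility,N,lambda,ploidy model inputs,
#'   as in [predict_site_occupancy()].
#' @param fragment_mean,fragment_sd,smooth_window profile parameters.
#' @param noise_sd standard deviation of the additive noise, in profile units
#'   (0 = deterministic output).
#' @param seed optional integer; when given, the noise is generated from this
#'   seed without disturbing the caller's RNG state.
#' @param kernel optional precomputed `fragment_kernel`.
#' @return numeric per-base profile.
#' @export
simulate_chip_profile <- function(filtered_sites, all_sites,
                                  accessibility = NULL, N, lambda,
                                  ploidy = 2L, fragment_mean = 200,
                                  fragment_sd = 200, smooth_window = 250,
                                  noise_sd = 0, seed = NULL, kernel = NULL) {
  occ <- predict_site_occupancy(filtered_sites, all_sites, accessibility,
                                N = N, lambda = lambda, ploidy = ploidy)
  L <- attr(all_sites, "seq_length")
  m <- attr(all_sites, "motif_length")
  centers <- occ$start + floor((m - 1) / 2)
  prof <- extend_occupancy_to_coverage(centers, occ$probability, L,
                                       kernel = kernel,
                                       fragment_mean = fragment_mean,
                                       fragment_sd = fragment_sd)
  prof <- smooth_profile(prof, smooth_window)
  add_truncated_noise(prof, noise_sd, seed)
}

#' Add zero-truncated Gaussian noise to a profile
#'
#' @param profile numeric signal.
#' @param noise_sd noise standard deviation (profile units).
#' @param seed optional integer seed, applied locally.
#' @return noisy profile, clipped at zero.
#' @export
add_truncated_noise <- function(profile, noise_sd, seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (noise_sd == 0) return(profile)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  pmax(0, profile + stats::rnorm(length(profile), 0, noise_sd))
}
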