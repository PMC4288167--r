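#' Bin a per-base profile into fixed-width means
#'
#' @param profile numeric per-base signal.
#' @param bin bin width, bp; the last bin may be shorter.
#' @return numeric vector of bin means.
#' @export
bin_profile <- function(profile, bin = 1000) {
  if (bin < 1) stop("'bin' must be >= 1")
  L <- length(profile)
  g <- (seq_len(L) - 1L) %/% as.integer(bin)
  as.numeric(rowsum(profile, g)) / tabulate(g + 1L)
}

#' Pearson correlation between two profiles
#'
#' @param pred,obs equal-length numeric profiles.
#' @return correlation coefficient in \[-1, 1\]. If either profile has zero
#'   variance the coefficient is undefined and an error of condition class
#'   `tfocc_zero_variance` is raised (rather than returning a number).
#' @export
pearson_correlation <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("profiles have different lengths")
  if (length(pred) < 2L)
    stop("need at least 2 values to correlate")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop(structure(class = c("tfocc_zero_variance", "error", "condition"),
                   list(message = "zero variance: correlation undefined",
                        call = sys.call(-1))))
  stats::cor(pred, obs)
}

#' Mean squared error between profiles over fixed-width bins
#'
#' Both profiles are averaged over `bin`-bp windows and compared by mean
#' squared difference. The `normalization` argument controls how the profiles
#' are brought to a common scale first:
#' \describe{
#'   \item{`"none"`}{profiles are compared as-is. This is the default: the
#'     model emits occupancy-scale signal and an amplitude mismatch is
#'     informative (it is what makes the MSE sensitive to the molecule number
#'     N).}
#'   \item{`"mean"`}{each profile divided by its own mean; scale-invariant.}
#'   \item{`"max"`}{each profile divided by its own maximum.}
#' }
#'
#' @param pred,obs equal-length numeric per-base profiles.
#' @param bin bin width, bp (a region shorter than one bin is compared as a
#'   single bin, with a warning).
#' @param normalization `"none"`, `"mean"` or `"max"`.
#' @return non-negative mean squared error; 0 iff the normalised binned
#'   profiles are identical.
#' @export
normalized_mse <- function(pred, obs, bin = 1000,
                           normalization = c("none", "mean", "max")) {
  normalization <- match.arg(normalization)
  if (length(pred) != length(obs))
    stop("profiles have different lengths")
  if (length(pred) < bin)
    warning("region shorter than one bin: comparing single-bin means")
  pb <- bin_profile(pred, bin)
  ob <- bin_profile(obs, bin)
  mean((.normalize_profile(pb, normalization) -
          .normalize_profile(ob, normalization))^2)
}

.normalize_profile <- function(v, normalization) {
  switch(normalization,
    none = v,
    mean = {
      mu <- mean(v)
      if (mu == 0) stop("cannot mean-normalize an all-zero profile")
      v / mu
    },
    max = {
      mx <- max(v)
      if (mx == 0) stop("cannot max-normalize an all-zero profile")
      v / mx
    })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the maximum ECDF
#' difference and its asymptotic p-value, flagging small samples where the
#' asymptotic p-value is unreliable.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param min_reliable minimum per-sample size below which the p-value is
#'   flagged unreliable.
#' @return list with `statistic`, `p_value` and `unreliable`.
#' @export
ks_two_sample <- function(x, y, min_reliable = 8L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(kt$statistic),
       p_value = unname(kt$p.value),
       unreliable = min(length(x), length(y)) < min_reliable)
}
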