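# Independent oracles and small constructors used across the tests.

# Scalar evaluation of the binding-probability formula, written as plain
# loops: deliberately independent of the vectorized implementation.
scalar_occupancy <- function(j, scores, acc, N, lambda, n_slots, ploidy) {
  weight <- function(s) exp(s * log(2) / lambda)
  total <- 0
  for (i in seq_along(scores)) total <- total + acc[i] * weight(scores[i])
  avg <- total / n_slots
  num <- N * acc[j] * weight(scores[j])
  num / (num + n_slots * ploidy * avg)
}

# Single-molecule Boltzmann distribution over all site slots (ploidy copies
# of each strandwise window, masked slots weightless).
boltzmann_distribution <- function(scores, acc, lambda, ploidy) {
  x <- acc * exp(scores * log(2) / lambda)
  x / (ploidy * sum(x))
}

# Minimal tfbs_sites-like object from raw scores, for unit-level checks of
# the occupancy operations.
fake_sites <- function(scores, n_slots = length(scores), m = 1L,
                       seq_length = length(scores) + m - 1L) {
  df <- data.frame(start = seq_along(scores),
                   strand = rep("+", length(scores)), score = scores)
  structure(df, chrom = "toy", motif_length = m, seq_length = seq_length,
            n_slots = n_slots,
            score_range = if (length(scores)) range(scores)
                          else c(NA_real_, NA_real_),
            class = c("tfbs_sites", "data.frame"))
}

# A tiny sharp PWM for scanning tests: 2 positions, A then C strongly
# preferred.
tiny_pwm <- function() {
  build_pwm(matrix(c(8, 1, 1, 1,
                     1, 8, 1, 1), nrow = 4), pseudo_count = 1, name = "tiny")
}

random_genome <- function(L, seed) {
  withr_seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

withr_seed <- function(seed) set.seed(seed)
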