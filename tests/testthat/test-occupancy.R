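test_that("genomic Boltzmann average is the mean statistical weight", {
  # weights 2^1 = 2 and 2^3 = 8 at lambda 1 -> mean 5
  s <- fake_sites(c(1, 3))
  expect_equal(genomic_boltzmann_average(s, NULL, lambda = 1), 5)
  # zero scores give weight 1 regardless of lambda
  z <- fake_sites(c(0, 0))
  for (lam in c(0.3, 1, 4))
    expect_equal(genomic_boltzmann_average(z, NULL, lam), 1)
  # masked slots dilute the average through n_slots
  s4 <- fake_sites(c(1, 3), n_slots = 4)
  expect_equal(genomic_boltzmann_average(s4, NULL, 1), 2.5)
})

test_that("an all-inaccessible genome is rejected", {
  s <- fake_sites(c(1, 2, 3))
  expect_error(
    genomic_boltzmann_average(s, NULL, 1,
                              site_accessibility = c(0, 0, 0)),
    "inaccessible")
  expect_error(boltzmann_weight(1, lambda = 0), "positive")
  expect_error(occupancy_probability(1, 1, N = -5, lambda = 1, avg = 1,
                                     n_slots = 10), "positive")
})

test_that("occupancy probability has the closed-form fixed points", {
  # closed chromatin binds nothing
  expect_equal(occupancy_probability(5, 0, N = 1000, lambda = 1, avg = 2,
                                     n_slots = 100), 0)
  # N equal to the competition term gives exactly one half
  avg <- 3; n_slots <- 50; ploidy <- 2; w <- 2; lam <- 1.3
  N_half <- n_slots * ploidy * avg / boltzmann_weight(w, lam)
  expect_equal(occupancy_probability(w, 1, N_half, lam, avg, n_slots, ploidy),
               0.5)
})

test_that("probabilities stay in [0,1] and are monotone in N, w and a", {
  set.seed(71)
  for (rep in 1:20) {
    w <- runif(1, -15, 15); a <- runif(1); lam <- runif(1, 0.25, 5)
    avg <- runif(1, 1e-3, 10); ns <- sample(10:1e5, 1)
    N1 <- 10^runif(1, 0, 5)
    p1 <- occupancy_probability(w, a, N1, lam, avg, ns)
    expect_gte(p1, 0); expect_lte(p1, 1)
    # strictly increasing in N (when accessible)
    if (a > 0) {
      expect_gt(occupancy_probability(w, a, N1 * 2, lam, avg, ns), p1)
      expect_gt(occupancy_probability(w + 1, a, N1, lam, avg, ns), p1)
    }
    expect_gte(occupancy_probability(w, min(1, a + 0.1), N1, lam, avg, ns), p1)
  }
})

test_that("vectorized occupancy equals the independent scalar formula", {
  set.seed(42)
  g <- random_genome(3000, seed = 42)
  acc <- generate_accessibility(3000, 0.3, 300)
  all_sites <- score_sequence(default_pwm(), g)
  a_site <- tfocc:::.site_accessibility(all_sites, acc)
  for (k in 1:5) {
    N <- 10^runif(1, 0, 5); lam <- runif(1, 0.25, 5)
    occ <- predict_site_occupancy(
      filter_by_relative_score(all_sites, 0.5), all_sites, acc,
      N = N, lambda = lam)
    idx <- sample(nrow(occ), 10)
    for (j in idx) {
      pos <- match(paste(occ$start[j], occ$strand[j]),
                   paste(all_sites$start, all_sites$strand))
      expect_equal(occ$probability[j],
                   scalar_occupancy(pos, all_sites$score, a_site, N, lam,
                                    attr(all_sites, "n_slots"), 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("total occupancy approaches N in the low-abundance limit", {
  g <- random_genome(10000, seed = 9)
  pwm <- default_pwm()
  sites <- score_sequence(pwm, g)
  acc <- generate_accessibility(10000, 0.5, 500)
  a_site <- tfocc:::.site_accessibility(sites, acc)
  ploidy <- 2; N <- 2
  avg <- genomic_boltzmann_average(sites, acc, 1.5)
  p <- occupancy_probability(sites$score, a_site, N, 1.5, avg,
                             attr(sites, "n_slots"), ploidy)
  expect_equal(ploidy * sum(p), N, tolerance = 0.01)
})

test_that("large lambda washes out sequence specificity", {
  s <- fake_sites(c(-10, 0, 12))
  avg <- genomic_boltzmann_average(s, NULL, lambda = 1e9)
  p <- occupancy_probability(s$score, 1, N = 50, lambda = 1e9, avg = avg,
                             n_slots = 3)
  expect_lt(diff(range(p)), 1e-6)
})

test_that("doubling N strictly increases every reported occupancy", {
  g <- random_genome(5000, seed = 13)
  acc <- generate_accessibility(5000, 0.4, 400)
  model <- occupancy_model(g, default_pwm(), acc, threshold = 0.5)
  p1 <- site_probabilities(model, 100, 1.5)
  p2 <- site_probabilities(model, 200, 1.5)
  open <- model$site_acc > 0
  expect_true(all(p2[open] > p1[open]))
  expect_true(all(p2[!open] == 0))
})

test_that("naked DNA equals an all-ones accessibility track", {
  g <- random_genome(4000, seed = 21)
  m1 <- occupancy_model(g, default_pwm(), NULL, threshold = 0.6)
  m2 <- occupancy_model(g, default_pwm(),
                        accessibility_track(rep(1, 4000), "binary"),
                        threshold = 0.6)
  expect_equal(site_probabilities(m1, 500, 2), site_probabilities(m2, 500, 2))
})

test_that("read-density accessibility map is monotone with a 0.5 midpoint", {
  d <- c(0, 0.5, 1, 2, 4, 8, 100)
  a <- accessibility_from_read_density(d, midpoint = 2)
  expect_equal(a[[1]], 0)
  expect_true(all(diff(as.numeric(a)) >= 0))
  expect_equal(as.numeric(a)[4], 0.5)
  expect_lte(as.numeric(accessibility_from_read_density(rep(0, 10)))[1], 0.05)
  expect_error(accessibility_from_read_density(c(-1, 2)), "non-negative")
  # midpoint defaults to the median of positive densities
  d2 <- c(0, 1, 2, 3, 4, 5)
  a2 <- accessibility_from_read_density(d2)   # midpoint = median(1:5) = 3
  expect_equal(as.numeric(a2)[d2 == 3], 0.5)
})
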