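test_that("pearson correlation matches the textbook formula", {
  expect_equal(pearson_correlation(1:10, 1:10), 1)
  expect_equal(pearson_correlation(1:10, -(1:10) + 7), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  n <- 4
  manual <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(pearson_correlation(x, y), manual, tolerance = 1e-12)
  err <- tryCatch(pearson_correlation(rep(1, 5), 1:5), error = identity)
  expect_s3_class(err, "tfocc_zero_variance")
})

test_that("binned MSE honours its normalization modes", {
  set.seed(4)
  obs <- runif(3000)
  expect_equal(normalized_mse(obs, obs), 0)
  # mean normalization is scale invariant by construction
  expect_equal(normalized_mse(2 * obs, obs, normalization = "mean"), 0)
  expect_equal(normalized_mse(5 * obs, obs, normalization = "max"), 0)
  expect_gt(normalized_mse(2 * obs, obs, normalization = "none"), 0)
  # three-bin toy computed by hand: bin means 1, 2, 3 vs 2, 2, 2
  pred <- rep(c(1, 2, 3), each = 1000)
  obs3 <- rep(2, 3000)
  expect_equal(normalized_mse(pred, obs3, normalization = "none"),
               ((1 - 2)^2 + 0 + (3 - 2)^2) / 3)
  # same toy under mean normalization: both profiles have mean 2
  expect_equal(normalized_mse(pred, obs3, normalization = "mean"),
               ((0.5 - 1)^2 + 0 + (1.5 - 1)^2) / 3)
  expect_warning(normalized_mse(c(1, 2), c(1, 3), bin = 10), "single-bin")
})

test_that("correlation is affine invariant; mean-MSE is scale invariant", {
  set.seed(5)
  a <- runif(2000); b <- runif(2000)
  expect_equal(pearson_correlation(a, b),
               pearson_correlation(3 * a + 2, b), tolerance = 1e-12)
  expect_equal(normalized_mse(a, b, normalization = "mean"),
               normalized_mse(7 * a, b, normalization = "mean"),
               tolerance = 1e-12)
})

test_that("two-sample KS statistic is the maximum ECDF gap", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:4, 11:14)$statistic, 1)
  k <- ks_two_sample(c(1, 2, 3), c(2, 3, 4))
  expect_equal(k$statistic, 1 / 3, tolerance = 1e-12)
  expect_true(k$unreliable)
  expect_false(ks_two_sample(rnorm(50), rnorm(50))$unreliable)
  expect_error(ks_two_sample(1, 1:5), "at least 2")
})

test_that("a 1x1 grid reproduces direct metric calls", {
  fx <- make_fixture(synthetic_spec(genome_length = 30000,
                                    n_planted_sites = 10,
                                    sites_in_accessible = TRUE, seed = 3))
  g <- grid_search(fx$observed, fx$model, N_grid = 3000, lambda_grid = 1.25,
                   noise_model = "none")
  prof <- predict_chip_profile(fx$model, 3000, 1.25)
  acc_bin <- bin_profile(as.numeric(fx$accessibility), 1000)
  dom <- which(acc_bin > 0)
  pb <- bin_profile(prof, 1000)[dom]
  ob <- bin_profile(fx$observed, 1000)[dom]
  expect_equal(g$rho[1, 1], pearson_correlation(pb, ob), tolerance = 1e-12)
  expect_equal(g$mse[1, 1], mean((pb - ob)^2), tolerance = 1e-12)
})

test_that("noiseless self-consistency: the true cell minimises the MSE", {
  spec <- synthetic_spec(genome_length = 60000, n_planted_sites = 20,
                         noise_sd = 0, sites_in_accessible = TRUE, seed = 8)
  fx <- make_fixture(spec)
  g <- grid_search(fx$observed, fx$model,
                   N_grid = c(500, 2000, 5000, 20000, 1e5),
                   lambda_grid = c(0.75, 1.25, 1.5, 2, 3))
  opt <- select_optimum(g)
  expect_equal(opt$N_opt, 5000)
  expect_equal(opt$lambda_opt, 1.5)
  expect_equal(opt$mse_at_opt, 0, tolerance = 1e-12)
  expect_error(grid_search(rep(2, fx$model$L), fx$model), "degenerate")
})

test_that("optimum selection follows the band-intersection rule", {
  mk <- function(rho, mse, N = c(10, 100, 1000), lam = c(1, 2, 3)) {
    structure(list(N_grid = N, lambda_grid = lam, rho = rho, mse = mse,
                   noise_sigma = 0, bin = 1000, normalization = "none",
                   metric_domain = 1L, noise_model = "none"),
              class = "occupancy_grid")
  }
  # one cell is both rho-max and mse-min
  rho <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3)
  mse <- matrix(c(9, 9, 9, 9, 1, 9, 9, 9, 9), 3)
  opt <- select_optimum(mk(rho, mse))
  expect_equal(opt$N_opt, 100); expect_equal(opt$lambda_opt, 2)
  expect_false(opt$intersection_empty)
  expect_gte(nrow(opt$intersection), 1)
  expect_true(all(opt$mse_at_opt <= opt$intersection$mse))
  # band fraction 1: intersection covers the grid, optimum = global mse min
  opt1 <- select_optimum(mk(rho, mse), band_fraction = 1)
  expect_equal(nrow(opt1$intersection), 9)
  expect_equal(opt1$mse_at_opt, 1)
  # disjoint bands at 0.12: best rho cells have terrible mse and vice versa
  rho2 <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3)
  mse2 <- matrix(c(9, 5, 5, 5, 5, 5, 5, 5, 0.1), 3)
  opt2 <- select_optimum(mk(rho2, mse2))
  expect_true(opt2$intersection_empty)
  expect_equal(opt2$N_opt, 1000)   # global mse minimum
  expect_equal(opt2$lambda_opt, 3)
  # flat grid: degenerate flag, first cell
  opt3 <- select_optimum(mk(matrix(0.5, 3, 3), matrix(2, 3, 3)))
  expect_true(opt3$degenerate)
  expect_equal(opt3$N_opt, 10)
  # ties break towards smaller N then smaller lambda
  opt4 <- select_optimum(mk(matrix(1, 3, 3), matrix(1, 3, 3)))
  expect_equal(opt4$N_opt, 10); expect_equal(opt4$lambda_opt, 1)
})

test_that("region filtering uses the genome-wide background", {
  L <- 10000
  acc <- accessibility_track(rep(1, L), "binary")
  # signal concentrated in regions 3 and 7 of ten 1-kb regions
  obs <- rep(0.1, L)
  obs[2001:3000] <- 5 + sin(1:1000 / 50)       # structured peaks, not flat
  obs[6001:7000] <- 4 + cos(1:1000 / 80)
  pred <- obs + rnorm(L, 0, 0.01)
  rs <- genome_wide_regions(obs, pred, acc, region_size = 1000,
                            background_mult = 1, bin = 100)
  expect_equal(nrow(rs), 10)
  expect_equal(which(rs$passes_background), c(3, 7))
  expect_true(all(rs$rho[c(3, 7)] > 0.9))
  # uniform signal: none passes >B strictly, all pass >0.5B
  uni <- rep(2, L)
  r1 <- genome_wide_regions(uni, uni, acc, region_size = 1000,
                            background_mult = 1)
  expect_false(any(r1$passes_background))
  r05 <- genome_wide_regions(uni, uni, acc, region_size = 1000,
                             background_mult = 0.5)
  expect_true(all(r05$passes_background))
  # fully inaccessible regions are dropped
  acc2 <- accessibility_track(c(rep(0, 5000), rep(1, 5000)), "binary")
  r2 <- genome_wide_regions(obs, pred, acc2, region_size = 1000)
  expect_equal(nrow(r2), 5)
  expect_true(all(r2$start > 5000))
})
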