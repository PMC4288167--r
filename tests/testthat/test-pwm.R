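test_that("pseudo-count is split by background before normalising", {
  # column (4,0,0,0), pseudo-count 1, uniform background:
  # f_A = (4 + 0.25) / 5 = 0.85, score_A = log2(0.85 / 0.25)
  pwm <- build_pwm(matrix(c(4, 0, 0, 0), nrow = 4), pseudo_count = 1)
  expect_equal(unname(pwm$freq["A", 1]), 0.85)
  expect_equal(unname(pwm$mat["A", 1]), log2(0.85 / 0.25), tolerance = 1e-12)
  expect_equal(unname(pwm$mat["A", 1]), 1.766, tolerance = 1e-3)
  # uniform counts with uniform background score zero everywhere
  u <- build_pwm(matrix(10, 4, 3))
  expect_true(all(abs(u$mat) < 1e-12))
})

test_that("degenerate count matrices are rejected", {
  expect_error(build_pwm(matrix(c(0, 0, 0, 0), nrow = 4), pseudo_count = 0),
               "pseudo_count")
  expect_error(build_pwm(matrix(1, 3, 2)), "4 rows")
  expect_error(build_pwm(matrix(1, 4, 2), background = c(0.5, 0.5, 0, 0)),
               "background")
})

test_that("information content is the summed column relative entropy", {
  expect_equal(information_content(build_pwm(matrix(10, 4, 5))), 0)
  # a near-deterministic column approaches the 2-bit maximum
  sharp <- build_pwm(matrix(c(1e7, 0, 0, 0), nrow = 4), pseudo_count = 1)
  expect_equal(information_content(sharp), 2, tolerance = 1e-4)
  # independent recomputation from the frequency matrix
  pwm <- default_pwm()
  ic_manual <- 0
  for (k in seq_len(ncol(pwm$freq)))
    for (b in 1:4)
      ic_manual <- ic_manual + pwm$freq[b, k] * log2(pwm$freq[b, k] / 0.25)
  expect_equal(information_content(pwm), unname(ic_manual), tolerance = 1e-12)
})

test_that("scanning scores every window on both strands", {
  pwm <- build_pwm(matrix(c(4, 0, 0, 0), nrow = 4), pseudo_count = 1)
  s <- score_sequence(pwm, "AC")
  plus <- s[s$strand == "+", ]
  expect_equal(plus$score, unname(pwm$mat[c("A", "C"), 1]))
  # minus strand of "AC" reads "GT"
  minus <- s[s$strand == "-", ]
  expect_equal(minus$score, unname(pwm$mat[c("T", "G"), 1]))
  expect_equal(attr(s, "n_slots"), 4L)
  expect_no_error(score_sequence(pwm, "A", both_strands = FALSE))
  expect_error(score_sequence(tiny_pwm(), "A"), "shorter than the motif")
})

test_that("windows containing N are masked but keep their slot", {
  pwm <- tiny_pwm()
  s <- score_sequence(pwm, "NNNN")
  expect_equal(nrow(s), 0L)
  expect_equal(attr(s, "n_slots"), 6L)
  s2 <- score_sequence(pwm, "ACNAC")
  # windows 2 and 3 touch the N on each strand
  expect_equal(sort(unique(s2$start)), c(1L, 4L))
})

test_that("strand scores obey reverse-complement symmetry", {
  pwm <- default_pwm()
  g <- random_genome(300, seed = 11)
  s <- score_sequence(pwm, g)
  m <- ncol(pwm$mat)
  minus <- s[s$strand == "-", ]
  for (i in sample(nrow(minus), 20)) {
    win <- substr(g, minus$start[i], minus$start[i] + m - 1L)
    rc <- reverse_complement(win)
    manual <- sum(vapply(seq_len(m), function(k)
      pwm$mat[substr(rc, k, k), k], numeric(1)))
    expect_equal(minus$score[i], manual, tolerance = 1e-12)
  }
})

test_that("scanner agrees with the Biostrings scoring oracle", {
  pwm <- default_pwm()
  g <- random_genome(500, seed = 3)
  s <- score_sequence(pwm, g, both_strands = FALSE)
  mat <- pwm$mat
  storage.mode(mat) <- "double"
  oracle <- Biostrings::PWMscoreStartingAt(mat, Biostrings::DNAString(g),
                                           starting.at = s$start)
  expect_equal(s$score, unname(oracle), tolerance = 1e-9)
})

test_that("relative-score filter implements both threshold modes", {
  s <- fake_sites(c(-10, 0, 8, 9))
  # literal range mode: threshold 0.7 * (9 - (-10)) = 13.3 exceeds every score
  lit <- filter_by_relative_score(s, 0.7, mode = "absolute_range")
  expect_equal(nrow(lit), 0L)
  # literal mode at fraction 0 keeps non-negative scores
  lit0 <- filter_by_relative_score(s, 0, mode = "absolute_range")
  expect_equal(lit0$score, c(0, 8, 9))
  # offset mode: threshold -10 + 0.7 * 19 = 3.3
  off <- filter_by_relative_score(s, 0.7)
  expect_equal(off$score, c(8, 9))
  expect_equal(attr(off, "threshold"), 3.3)
})

test_that("filtering is idempotent and monotone in the fraction", {
  g <- random_genome(2000, seed = 5)
  s <- score_sequence(default_pwm(), g)
  f1 <- filter_by_relative_score(s, 0.6)
  f2 <- filter_by_relative_score(f1, 0.6)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  for (fr in c(0.5, 0.7, 0.9)) {
    lo <- filter_by_relative_score(s, fr - 0.1)
    hi <- filter_by_relative_score(s, fr)
    expect_true(all(hi$score %in% lo$score))
    expect_lte(nrow(hi), nrow(lo))
  }
  empty <- fake_sites(numeric(0))
  expect_warning(res <- filter_by_relative_score(empty, 0.5), "no sites")
  expect_equal(nrow(res), 0L)
})

test_that("uniform PWM scores every window zero", {
  u <- build_pwm(matrix(7, 4, 6))
  s <- score_sequence(u, random_genome(100, seed = 2))
  expect_true(all(abs(s$score) < 1e-9))
})
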