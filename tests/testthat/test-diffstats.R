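test_that("F_ST hits its limits and the hand-worked value", {
  fr <- make_freqs(pos = 1:4,
                   m = list(c(A = 10, T = 10), c(A = 20), c(A = 16, T = 4),
                            c(A = 20)),
                   f = list(c(A = 10, T = 10), c(T = 20), c(A = 4, T = 16),
                            c(A = 20)))
  fst <- site_fst(fr)
  expect_equal(fst[1], 0)            # identical pools
  expect_equal(fst[2], 1)            # fixed difference: pi_within = 0
  # 16:4 vs 4:16 at C = 20 each: pi_m = pi_f = (20/19)*0.32,
  # pi_total = (40/39)*0.5, F_ST = 0.34316
  expect_lt(abs(fst[3] - 0.3432), 1e-4)
  expect_true(is.na(fst[4]))         # monomorphic across both pools

  low <- make_freqs(pos = 1, m = list(c(A = 1)), f = list(c(A = 10, T = 10)))
  expect_true(is.na(site_fst(low)))  # coverage < 2 in a pool
})

test_that("F_ST is symmetric under pool swap", {
  set.seed(11)
  n <- 1000
  a_m <- rbinom(n, 30, runif(n)); n_m <- 30
  a_f <- rbinom(n, 40, runif(n)); n_f <- 40
  fr <- data.frame(a_male = a_m, n_male = n_m, a_female = a_f, n_female = n_f,
                   uncomputable = FALSE)
  sw <- data.frame(a_male = a_f, n_male = n_f, a_female = a_m, n_female = n_m,
                   uncomputable = FALSE)
  expect_equal(site_fst(fr), site_fst(sw))
})

test_that("Fisher p matches the worked examples", {
  fr <- make_freqs(pos = 1:3,
                   m = list(c(A = 10, T = 10), c(A = 5, T = 5), c(A = 1)),
                   f = list(c(A = 5, T = 5), c(A = 10), c(T = 1)))
  p <- site_fisher(fr)
  expect_equal(p[1], 1)                        # identical proportions
  # margins (10,10) x (15,5): extreme tables a=5 and a=10 each have
  # probability 3003/184756; two-sided p = 2 * 3003/184756
  expect_equal(p[2], 2 * 3003 / 184756, tolerance = 1e-12)
  expect_equal(p[3], 1)                        # 1:0 vs 0:1, both tables tie
})

test_that("Fisher p equals stats::fisher.test across random tables", {
  set.seed(7)
  n <- 250
  a <- rbinom(n, 25, 0.4); b <- rbinom(n, 25, 0.4)
  c_ <- rbinom(n, 25, 0.6); d <- rbinom(n, 25, 0.3)
  keep <- (a + b) > 0 & (c_ + d) > 0
  fr <- data.frame(a_male = a, n_male = a + b, a_female = c_,
                   n_female = c_ + d)[keep, ]
  p <- site_fisher(fr)
  ref <- mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  }, fr$a_male, fr$n_male - fr$a_male, fr$a_female,
     fr$n_female - fr$a_female)
  expect_equal(p, unname(ref), tolerance = 1e-8)
})

test_that("widening the frequency gap never increases the Fisher p", {
  # coverage 20/20; male minor count 10+d vs female 10-d, d = 0..10
  d <- 0:10
  fr <- data.frame(a_male = 10 + d, n_male = 20, a_female = 10 - d,
                   n_female = 20)
  p <- site_fisher(fr)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("windowed means average the right sites", {
  stats_df <- data.frame(chrom = c("LG1", "LG1", "LG1", "LG2"),
                         pos = c(100L, 9000L, 10001L, 5L),
                         fst = c(0.2, 0.4, 0.6, NA),
                         fisher_p = c(0.1, 0.01, 0.5, NA))
  stats_df$neg_log10_p <- -log10(stats_df$fisher_p)
  w <- window_mean(stats_df, window_bp = 10000,
                   chrom_lengths = c(LG1 = 30000, LG2 = 10000))
  expect_equal(nrow(w), 4L)
  expect_equal(w$mean_fst[1], 0.3)             # sites 100 and 9000
  expect_equal(w$mean_fst[2], 0.6)             # boundary site 10001 -> win 2
  expect_true(is.na(w$mean_fst[3]))            # empty window
  expect_equal(w$n_sites, c(2L, 1L, 0L, 0L))
  expect_error(window_mean(stats_df, window_bp = 0), "positive")
})
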