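# build an expression table with prescribed bias counts inside/outside a
# unit region on LG1 (region = [1, 1e6]); FPKMs are set so classification
# recovers the intended bias
make_expr_records <- function(male_in, female_in, male_out, female_out) {
  n <- male_in + female_in + male_out + female_out
  inside <- rep(c(TRUE, FALSE), c(male_in + female_in, male_out + female_out))
  male <- c(rep(c(TRUE, FALSE), c(male_in, female_in)),
            rep(c(TRUE, FALSE), c(male_out, female_out)))
  mid <- ifelse(inside, 5e5, 5e6)
  data.frame(gene_id = sprintf("g%06d", seq_len(n)), chrom = "LG1",
             start = mid - 500, end = mid + 499,
             fpkm_male = ifelse(male, 2, 1),
             fpkm_female = ifelse(male, 1, 2), stringsAsFactors = FALSE)
}

unit_region <- function() region_row(start_bp = 1, end_bp = 1e6)

test_that("bias classification follows the FPKM rules", {
  expect_equal(classify_bias(6.78248, 5.16947), "male")
  expect_equal(classify_bias(0.03, 0.04), "excluded")
  # zero in one sex, expressed in the other: biased toward the expressed sex
  expect_equal(classify_bias(0, 0.370072), "female")
  expect_equal(classify_bias(1.5, 1.5), "tie")
  # one sex above threshold is enough to escape exclusion
  expect_equal(classify_bias(0.2, 0.01), "male")
  expect_error(classify_bias(-1, 2), "non-negative")
})

test_that("Yates chi-square matches the printed reproduction and base R", {
  t1 <- yates_chi2(68, 162, 7977, 13375)
  expect_equal(round(t1$chi2, 2), 5.58)
  expect_gte(t1$chi2, 5.57); expect_lte(t1$chi2, 5.60)
  expect_lt(t1$p, 0.05)
  ref <- stats::chisq.test(matrix(c(68, 162, 7977, 13375), 2, byrow = TRUE),
                           correct = TRUE)
  expect_equal(t1$chi2, unname(ref$statistic))
  expect_equal(t1$p, unname(ref$p.value))

  # proportional table scores exactly 0 under the truncated correction
  expect_equal(yates_chi2(10, 10, 100, 100)$chi2, 0)

  # diagonal tables grow without bound: hand-evaluated 16.2 and 196.02
  expect_equal(yates_chi2(0, 10, 10, 0)$chi2, 4 * 4.5^2 / 5)
  expect_equal(yates_chi2(0, 100, 100, 0)$chi2, 4 * 49.5^2 / 50)

  expect_error(yates_chi2(0, 0, 5, 5), "degenerate")
})

test_that("chi-square is invariant under swapping rows and columns", {
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(4, 20) + 1
    a <- yates_chi2(x[1], x[2], x[3], x[4])$chi2
    b <- yates_chi2(x[4], x[3], x[2], x[1])$chi2
    expect_equal(a, b)
  }
})

test_that("enrichment report reproduces the block-vs-genome construction", {
  rec <- make_expr_records(68, 162, 7977 - 68, 13375 - 162)
  rep1 <- enrichment_report(rec, unit_region(), background = "genomewide")
  expect_equal(rep1$male_in, 68L)
  expect_equal(rep1$female_in, 162L)
  expect_equal(rep1$male_bg, 7977L)    # genome-wide background includes block
  expect_equal(rep1$female_bg, 13375L)
  expect_equal(round(rep1$chi2, 2), 5.58)
  expect_lt(rep1$p, 0.05)

  rep2 <- enrichment_report(rec, unit_region(), background = "outside")
  expect_equal(rep2$male_bg, 7977L - 68L)

  # strong enrichment: all inside female, balanced background
  rec3 <- make_expr_records(0, 50, 500, 500)
  rep3 <- enrichment_report(rec3, unit_region())
  expect_gt(rep3$chi2, 20)
  expect_lt(rep3$p, 0.05)
})

test_that("bias classes account for every input record", {
  set.seed(9)
  n <- 400
  rec <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "LG1",
                    start = seq_len(n) * 1e4, end = seq_len(n) * 1e4 + 999,
                    fpkm_male = round(rexp(n, 2), 3),
                    fpkm_female = round(rexp(n, 2), 3))
  rep <- enrichment_report(rec, unit_region())
  expect_equal(rep$male_all + rep$female_all + rep$n_ties + rep$n_excluded,
               n)

  # region without gene models: report exists, test is NA
  empty_reg <- region_row(chrom = "LG9", start_bp = 1, end_bp = 100)
  expect_true(is.na(enrichment_report(rec, empty_reg)$chi2))
})
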