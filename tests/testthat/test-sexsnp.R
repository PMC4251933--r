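freq_row <- function(f_male, f_female, cov_male = 30L, cov_female = 30L,
                     chrom = "LG1", pos = 100L) {
  data.frame(chrom = chrom, pos = pos, f_male = f_male, f_female = f_female,
             cov_male = cov_male, cov_female = cov_female,
             uncomputable = FALSE, stringsAsFactors = FALSE)
}

test_that("sex-pattern classification applies inclusive thresholds", {
  cases <- rbind(
    cbind(freq_row(0.5, 0.0), qual = TRUE),    # canonical XY signature
    cbind(freq_row(0.5, 0.5), qual = FALSE),   # female pool not fixed
    cbind(freq_row(0.3, 0.1), qual = TRUE),    # all bounds inclusive
    cbind(freq_row(0.7, 0.9), qual = TRUE),
    cbind(freq_row(0.29, 0.0), qual = FALSE),  # just below intermediate band
    cbind(freq_row(0.71, 0.0), qual = FALSE),
    cbind(freq_row(0.5, 0.11), qual = FALSE),  # just inside the open middle
    cbind(freq_row(0.5, 0.89), qual = FALSE))
  cases$pos <- seq_len(nrow(cases)) * 10L
  cl <- classify_sex_snps(cases)
  expect_equal(cl$sex_pattern, cases$qual)
})

test_that("coverage below 10 in either pool makes a site ineligible", {
  r <- rbind(freq_row(0.5, 0, cov_male = 9L, pos = 10L),
             freq_row(0.5, 0, cov_female = 9L, pos = 20L),
             freq_row(0.5, 0, cov_male = 10L, cov_female = 10L, pos = 30L))
  cl <- classify_sex_snps(r)
  expect_equal(cl$eligible, c(FALSE, FALSE, TRUE))
  expect_equal(cl$sex_pattern, c(FALSE, FALSE, TRUE))
})

test_that("zw polarity swaps which pool must be intermediate", {
  r <- rbind(freq_row(0.5, 0.0, pos = 10L),   # XY pattern
             freq_row(0.0, 0.5, pos = 20L))   # ZW pattern
  expect_equal(classify_sex_snps(r, polarity = "xy")$sex_pattern,
               c(TRUE, FALSE))
  expect_equal(classify_sex_snps(r, polarity = "zw")$sex_pattern,
               c(FALSE, TRUE))
})

test_that("tightening the intermediate band never adds qualifying sites", {
  set.seed(3)
  n <- 500
  r <- freq_row(runif(n), runif(n), pos = seq_len(n) * 10L,
                cov_male = rpois(n, 30), cov_female = rpois(n, 30))
  wide <- classify_sex_snps(r, intermediate = c(0.3, 0.7))$sex_pattern
  tight <- classify_sex_snps(r, intermediate = c(0.4, 0.6))$sex_pattern
  expect_true(all(!tight | wide))
  expect_lte(sum(tight), sum(wide))
})

test_that("window_scan tiles the dictionary and counts per window", {
  r <- rbind(freq_row(0.5, 0, pos = 100L),
             freq_row(0.5, 0, pos = 5000L),
             freq_row(0.5, 0, pos = 10001L),
             freq_row(0.9, 0, pos = 15000L))  # eligible but not qualifying
  cl <- classify_sex_snps(r)
  w <- window_scan(cl, chrom_lengths = c(LG1 = 40000, LG2 = 20000))
  expect_equal(nrow(w), 6L)
  expect_equal(w$n_sex_snps, c(2L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(w$n_eligible, c(2L, 2L, 0L, 0L, 0L, 0L))
  expect_equal(w$start, c(1, 10001, 20001, 30001, 1, 10001))

  # per-chromosome window sums equal the qualifying-SNP totals
  expect_equal(sum(w$n_sex_snps[w$chrom == "LG1"]), sum(cl$sex_pattern))

  expect_error(window_scan(cl, chrom_lengths = c(LG9 = 1e5)), "LG1")
  unsorted <- cl[c(2, 1, 3, 4), ]
  expect_error(window_scan(unsorted, chrom_lengths = c(LG1 = 4e4)),
               "sorted")
})

test_that("IGV tracks use 0-based half-open coordinates", {
  r <- freq_row(0.5, 0, pos = 100L)
  cl <- classify_sex_snps(r)
  path <- withr::local_tempfile(fileext = ".igv")
  write_igv_track(cl, path)
  lines <- readLines(path)
  expect_match(lines[1], "0-based")
  expect_equal(strsplit(lines[3], "\t")[[1]][2:3], c("99", "100"))

  w <- make_windows(c(5L))
  write_igv_track(w, path)
  row <- strsplit(readLines(path)[3], "\t")[[1]]
  expect_equal(row[2:3], c("0", "10000"))
  expect_equal(row[5], "5")

  # empty input -> header-only file
  write_igv_track(make_windows(integer(0)), path)
  expect_length(readLines(path), 2L)
})
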