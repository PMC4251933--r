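test_that("sync parsing handles canonical, empty and swapped-pool files", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("LG1\t100\tA\t10:0:0:0:0:0\t12:0:0:0:0:0",
               "LG1\t250\tC\t3:4:5:0:1:2\t0:0:8:0:0:0"), path)
  s <- read_sync(path)
  expect_s3_class(s, "pool_sync")
  expect_equal(s$pos, c(100L, 250L))
  expect_equal(s$m_A[1], 10L)
  expect_equal(s$f_A[1], 12L)
  expect_equal(s$m_N[2], 1L)
  expect_equal(s$m_del[2], 2L)

  swapped <- read_sync(path, pool_order = c("female", "male"))
  expect_equal(swapped$f_A[1], 10L)
  expect_equal(swapped$m_A[1], 12L)

  empty <- withr::local_tempfile(fileext = ".sync")
  writeLines(character(0), empty)
  expect_equal(nrow(read_sync(empty)), 0L)
})

test_that("malformed sync lines raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("LG1\t100\tA\t10:0:0:0:0:0\t12:0:0:0:0:0",
               "LG1\t200\tA\t10:0:x:0:0:0\t1:0:0:0:0:0"), path)
  expect_error(read_sync(path), "line 2")

  writeLines("LG1\t100\tA\t10:0:0:0:0:0", path)
  expect_error(read_sync(path), "pool columns")

  writeLines("LG1\t100\tA\t10:0:0:0\t1:0:0:0:0:0", path)
  expect_error(read_sync(path), "6 colon-separated")
})

test_that("write_sync round-trips canonical files byte-identically", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("LG1\t100\tA\t10:0:0:0:0:0\t12:0:0:0:0:0",
               "LG1\t250\tC\t3:4:5:0:1:2\t0:0:8:0:0:0",
               "LG2\t7\tG\t0:0:0:20:0:0\t1:2:3:4:5:6"), path)
  s <- read_sync(path)
  out <- withr::local_tempfile(fileext = ".sync")
  write_sync(s, out)
  expect_identical(readLines(out), readLines(path))

  # gzip-transparent read of a compressed copy
  gz <- withr::local_tempfile(fileext = ".sync.gz")
  write_sync(s, gz)
  expect_identical(read_sync(gz), s)
})

test_that("site frequencies report the pooled minor allele per pool", {
  # male A:10 T:10, female A:20 -> minor is T, f_male 0.5, f_female 0
  fr <- make_freqs(pos = 1, m = list(c(A = 10, T = 10)),
                   f = list(c(A = 20)))
  expect_equal(fr$major, "A")
  expect_equal(fr$minor, "T")
  expect_equal(fr$f_male, 0.5)
  expect_equal(fr$f_female, 0)
  expect_equal(fr$cov_male, 20L)
  expect_equal(fr$cov_female, 20L)

  # monomorphic: minor count 0 in both pools
  mono <- make_freqs(pos = 1, m = list(c(A = 20)), f = list(c(A = 20)))
  expect_equal(mono$f_male, 0)
  expect_equal(mono$f_female, 0)

  # zero coverage in both pools is flagged uncomputable
  zero <- make_freqs(pos = 1, m = list(c(A = 0)), f = list(c(A = 0)))
  expect_true(zero$uncomputable)
  expect_true(is.na(zero$f_male))
})

test_that("multi-allelic sites keep the two highest pooled counts", {
  # male A:8 T:8 C:4, female A:16 T:4 -> pooled A=24, T=12, C=4:
  # retained alleles A (major) and T (minor); C dropped and flagged
  fr <- make_freqs(pos = 1, m = list(c(A = 8, T = 8, C = 4)),
                   f = list(c(A = 16, T = 4)))
  expect_equal(fr$major, "A")
  expect_equal(fr$minor, "T")
  expect_true(fr$multiallelic)
  expect_equal(fr$n_male, 16L)         # C reads excluded from denominator
  expect_equal(fr$f_male, 8 / 16)
  expect_equal(fr$f_female, 4 / 20)
  expect_equal(fr$cov_male, 20L)       # full A/T/C/G coverage still reported
})

test_that("pooled-count ties break in alphabetical base order", {
  fr <- make_freqs(pos = 1, m = list(c(T = 5, G = 5)),
                   f = list(c(T = 5, G = 5)))
  expect_equal(fr$major, "G")  # G before T alphabetically
  expect_equal(fr$minor, "T")
})

test_that("frequencies are valid proportions with integer allele counts", {
  set.seed(42)
  n <- 200
  m <- lapply(seq_len(n), function(i) {
    stats::setNames(rpois(4, c(10, 5, 1, 0.2)), c("A", "T", "C", "G"))
  })
  f <- lapply(seq_len(n), function(i) {
    stats::setNames(rpois(4, c(12, 4, 1, 0.2)), c("A", "T", "C", "G"))
  })
  fr <- make_freqs(pos = seq_len(n), m = m, f = f)
  ok <- !is.na(fr$f_male)
  expect_true(all(fr$f_male[ok] >= 0 & fr$f_male[ok] <= 1))
  # f * retained depth recovers the integer minor-allele count
  expect_equal(fr$f_male[ok] * fr$n_male[ok], as.numeric(fr$a_male[ok]))
})
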