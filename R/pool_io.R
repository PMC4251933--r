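# Reading/writing Popoolation2-style sync files and per-site allele
# frequencies for a two-pool (male/female) design.

.BASES <- c("A", "T", "C", "G")
.SYNC_FIELDS <- c("A", "T", "C", "G", "N", "del")

#' Read a Popoolation2-style sync file
#'
#' Parses a tab-delimited sync file with one line per position:
#' `chrom TAB pos TAB ref TAB a:t:c:g:n:del TAB a:t:c:g:n:del`, one
#' count column per pool. Reading is gzip-transparent. Only two-pool
#' files are supported; by default the first pool column is the male
#' pool and the second the female pool.
#'
#' @param path Path to a sync file (optionally gzip-compressed).
#' @param pool_order Character vector of length 2 giving the sexes of
#'   the two pool columns in file order; either `c("male","female")`
#'   (default) or `c("female","male")`.
#' @return A data frame of class `pool_sync` with columns `chrom`,
#'   `pos`, `ref` and the six per-base read counts for each pool
#'   (`m_A` ... `m_del`, `f_A` ... `f_del`). Positions are 1-based.
#' @seealso [write_sync()], [site_frequencies()]
#' @export
read_sync <- function(path, pool_order = c("male", "female")) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  pool_order <- match.arg(paste(pool_order, collapse = ","),
                          c("male,female", "female,male"))
  con <- file(path, "r")  # file() decompresses gzip transparently
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_sync())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)[1L]
    if (nf[bad] < 4L) {
      stop("malformed sync line ", bad, ": expected at least 5 tab-separated ",
           "columns, found ", nf[bad])
    }
    stop("sync line ", bad, ": fewer than 2 pool columns")
  }
  mat <- t(vapply(fields, function(f) f[1:5], character(5)))
  pos <- suppressWarnings(as.integer(mat[, 2L]))
  if (anyNA(pos)) {
    stop("malformed sync line ", which(is.na(pos))[1L], ": non-integer position")
  }

  cnt1 <- .parse_counts(mat[, 4L])
  cnt2 <- .parse_counts(mat[, 5L])
  if (pool_order == "male,female") {
    cm <- cnt1; cf <- cnt2
  } else {
    cm <- cnt2; cf <- cnt1
  }
  colnames(cm) <- paste0("m_", .SYNC_FIELDS)
  colnames(cf) <- paste0("f_", .SYNC_FIELDS)

  out <- data.frame(chrom = mat[, 1L], pos = pos, ref = toupper(mat[, 3L]),
                    cm, cf, stringsAsFactors = FALSE)
  class(out) <- c("pool_sync", "data.frame")
  out
}

# parse "a:t:c:g:n:del" count strings into an integer matrix, reporting
# the 1-based line number of the first malformed field
.parse_counts <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  np <- lengths(parts)
  if (any(np != 6L)) {
    bad <- which(np != 6L)[1L]
    stop("malformed sync line ", bad, ": count field '", x[bad],
         "' does not have 6 colon-separated entries")
  }
  flat <- suppressWarnings(as.integer(unlist(parts, use.names = FALSE)))
  if (anyNA(flat)) {
    bad <- (which(is.na(flat))[1L] - 1L) %/% 6L + 1L
    stop("malformed sync line ", bad, ": non-integer count in '", x[bad], "'")
  }
  if (any(flat < 0L)) {
    bad <- (which(flat < 0L)[1L] - 1L) %/% 6L + 1L
    stop("malformed sync line ", bad, ": negative count in '", x[bad], "'")
  }
  matrix(flat, ncol = 6L, byrow = TRUE)
}

.empty_sync <- function() {
  cols <- c("chrom", "pos", "ref",
            paste0("m_", .SYNC_FIELDS), paste0("f_", .SYNC_FIELDS))
  out <- as.data.frame(setNames(
    c(list(character(0), integer(0), character(0)),
      rep(list(integer(0)), 12L)), cols))
  class(out) <- c("pool_sync", "data.frame")
  out
}

#' Write a sync table back to disk
#'
#' Inverse of [read_sync()]: writes `chrom TAB pos TAB ref` followed by
#' the two `a:t:c:g:n:del` count columns (male pool first unless
#' `pool_order` swaps them). Round-trips canonical files byte-identically.
#'
#' @param sync A `pool_sync` data frame from [read_sync()] or
#'   [simulate_genome()].
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @param pool_order As in [read_sync()].
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path, pool_order = c("male", "female")) {
  pool_order <- match.arg(paste(pool_order, collapse = ","),
                          c("male,female", "female,male"))
  fmt <- function(prefix) {
    cols <- as.matrix(sync[paste0(prefix, .SYNC_FIELDS)])
    apply(cols, 1L, paste, collapse = ":")
  }
  m <- if (nrow(sync)) fmt("m_") else character(0)
  f <- if (nrow(sync)) fmt("f_") else character(0)
  first <- if (pool_order == "male,female") m else f
  second <- if (pool_order == "male,female") f else m
  lines <- if (nrow(sync)) {
    paste(sync$chrom, sync$pos, sync$ref, first, second, sep = "\t")
  } else character(0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Per-site allele frequencies for the two pools
#'
#' Reduces each site to the two alleles with the highest pooled
#' (male + female) A/T/C/G counts (ties broken in alphabetical base
#' order) and reports, for each pool, the frequency of the pooled
#' *minor* allele. N and deletion counts are excluded from coverage and
#' frequencies. Sites where a third allele carries reads are flagged
#' `multiallelic`; its reads are dropped from the frequency denominator.
#' Sites with zero A/T/C/G coverage in both pools are flagged
#' `uncomputable` and are excluded by all downstream steps.
#'
#' @param sync A `pool_sync` data frame.
#' @return A data frame of class `site_freqs` with columns `chrom`,
#'   `pos`, `ref`, `major`, `minor`, minor-allele read counts `a_male`
#'   / `a_female`, retained two-allele depths `n_male` / `n_female`,
#'   frequencies `f_male` / `f_female` (minor-allele count over retained
#'   depth; `NA` when the retained depth is 0), full A/T/C/G coverages
#'   `cov_male` / `cov_female`, and flags `multiallelic`,
#'   `uncomputable`.
#' @export
site_frequencies <- function(sync) {
  n <- nrow(sync)
  m <- as.matrix(sync[paste0("m_", .BASES)])
  f <- as.matrix(sync[paste0("f_", .BASES)])
  if (n == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), major = character(0),
                      minor = character(0), a_male = integer(0),
                      a_female = integer(0), n_male = integer(0),
                      n_female = integer(0), f_male = numeric(0),
                      f_female = numeric(0), cov_male = integer(0),
                      cov_female = integer(0), multiallelic = logical(0),
                      uncomputable = logical(0))
    class(out) <- c("site_freqs", "data.frame")
    return(out)
  }
  # tie-break by alphabetical base order: scan columns A,C,G,T and take
  # the first maximum
  alpha <- c("A", "C", "G", "T")
  pooled <- (m + f)[, match(alpha, .BASES), drop = FALSE]
  i1 <- max.col(pooled, ties.method = "first")
  pooled2 <- pooled
  pooled2[cbind(seq_len(n), i1)] <- -1L
  i2 <- max.col(pooled2, ties.method = "first")
  major <- alpha[i1]
  minor <- alpha[i2]
  multiallelic <- rowSums(pooled > 0L) > 2L

  pick <- function(counts, base) counts[cbind(seq_len(n), match(base, .BASES))]
  a_m <- pick(m, minor); b_m <- pick(m, major)
  a_f <- pick(f, minor); b_f <- pick(f, major)
  n_m <- a_m + b_m
  n_f <- a_f + b_f
  cov_m <- rowSums(m)
  cov_f <- rowSums(f)

  out <- data.frame(chrom = sync$chrom, pos = sync$pos, ref = sync$ref,
                    major = major, minor = minor,
                    a_male = a_m, a_female = a_f,
                    n_male = n_m, n_female = n_f,
                    f_male = ifelse(n_m > 0L, a_m / n_m, NA_real_),
                    f_female = ifelse(n_f > 0L, a_f / n_f, NA_real_),
                    cov_male = cov_m, cov_female = cov_f,
                    multiallelic = multiallelic,
                    uncomputable = cov_m == 0L & cov_f == 0L,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_freqs", "data.frame")
  out
}
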