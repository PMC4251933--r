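# Per-site differentiation statistics between the male and female pools:
# pooled F_ST and the two-sided Fisher's exact test, plus windowed means.

#' Per-site pooled F_ST
#'
#' The classical pi-based pool-seq estimator. For a biallelic site with
#' pool coverages \eqn{C_m, C_f} (reads on the two retained alleles) and
#' minor-allele frequencies \eqn{f_m, f_f}:
#' \deqn{\pi_i = \frac{C_i}{C_i - 1}\,2 f_i (1 - f_i)}
#' \eqn{\pi_{within} = (\pi_m + \pi_f)/2}; \eqn{\pi_{total}} is computed
#' the same way from the summed counts with \eqn{C = C_m + C_f}; and
#' \eqn{F_{ST} = (\pi_{total} - \pi_{within}) / \pi_{total}}, clamped to
#' \eqn{[0, 1]}.
#'
#' @param freqs A `site_freqs` data frame from [site_frequencies()].
#' @return Numeric vector of F_ST values in `[0, 1]`; `NA` where the
#'   site is monomorphic across both pools (`pi_total = 0`), where
#'   either pool has fewer than 2 reads on the retained alleles, or
#'   where the site is uncomputable.
#' @export
site_fst <- function(freqs) {
  a_m <- freqs$a_male; n_m <- freqs$n_male
  a_f <- freqs$a_female; n_f <- freqs$n_female
  ok <- n_m >= 2L & n_f >= 2L & !freqs$uncomputable
  pi_hat <- function(a, n) (n / (n - 1)) * 2 * (a / n) * (1 - a / n)
  fst <- rep(NA_real_, nrow(freqs))
  if (any(ok)) {
    pi_m <- pi_hat(a_m[ok], n_m[ok])
    pi_f <- pi_hat(a_f[ok], n_f[ok])
    pi_w <- (pi_m + pi_f) / 2
    pi_t <- pi_hat(a_m[ok] + a_f[ok], n_m[ok] + n_f[ok])
    v <- ifelse(pi_t > 0, (pi_t - pi_w) / pi_t, NA_real_)
    fst[ok] <- pmin(pmax(v, 0), 1)
  }
  fst
}

# two-sided Fisher exact p for one 2x2 table (rows = pools, cols = the
# two retained alleles), by the "sum of small p" convention: sum of
# hypergeometric probabilities not exceeding that of the observed table
# (with the usual 1 + 1e-7 relative guard against floating-point ties).
.fisher_p1 <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  if (r1 == 0L || r2 == 0L) return(NA_real_)
  mw <- a + c                      # total reads on allele 1
  nb <- b + d                      # total reads on allele 2
  if (mw == 0L || nb == 0L) return(1)
  lo <- max(0L, r1 - nb)
  hi <- min(r1, mw)
  pr <- stats::dhyper(lo:hi, mw, nb, r1)
  min(sum(pr[pr <= pr[a - lo + 1L] * (1 + 1e-7)]), 1)
}

#' Two-sided Fisher's exact test on male vs female allele counts
#'
#' Tests, per site, whether the two pools differ in allele frequency.
#' The 2x2 table has pools as rows and the two retained alleles as
#' columns. Two-sidedness follows the "sum of small p" convention: the
#' p-value is the sum of the hypergeometric probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of
#' the observed table.
#'
#' @param freqs A `site_freqs` data frame from [site_frequencies()].
#' @return Numeric vector of p-values in `(0, 1]`; `NA` where a pool has
#'   no reads on the retained alleles.
#' @export
site_fisher <- function(freqs) {
  n <- nrow(freqs)
  if (n == 0L) return(numeric(0))
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p[i] <- .fisher_p1(freqs$a_male[i], freqs$n_male[i] - freqs$a_male[i],
                       freqs$a_female[i], freqs$n_female[i] - freqs$a_female[i])
  }
  p
}

#' Compute per-site F_ST and Fisher's exact statistics
#'
#' Convenience wrapper combining [site_fst()] and [site_fisher()] into
#' one site-statistics table.
#'
#' @param freqs A `site_freqs` data frame.
#' @return The input with columns `fst`, `fisher_p` and `neg_log10_p`
#'   appended.
#' @export
site_stats <- function(freqs) {
  freqs$fst <- site_fst(freqs)
  freqs$fisher_p <- site_fisher(freqs)
  freqs$neg_log10_p <- -log10(freqs$fisher_p)
  freqs
}

#' Windowed means of per-site statistics
#'
#' Averages `fst` and `neg_log10_p` in non-overlapping windows of
#' `window_bp`. Window `i` on a chromosome covers 1-based positions
#' `[(i-1)*window_bp + 1, i*window_bp]`. Windows with no computable
#' sites report `NA` means.
#'
#' @param stats A data frame from [site_stats()] (sorted by chromosome
#'   and position).
#' @param window_bp Window width in bp (> 0).
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   supplied, windows tile each chromosome fully, otherwise only up to
#'   the last observed position.
#' @return Data frame with `chrom`, `win_index`, `start`, `end`,
#'   `mean_fst`, `mean_neglog10p`, `n_sites` (sites with a computable
#'   Fisher p in the window).
#' @export
window_mean <- function(stats, window_bp = 10000, chrom_lengths = NULL) {
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp <= 0) {
    stop("window_bp must be a single positive number")
  }
  .check_sorted(stats)
  tiles <- .window_tiles(stats, window_bp, chrom_lengths)
  if (nrow(tiles) == 0L) return(cbind(tiles, mean_fst = numeric(0),
                                      mean_neglog10p = numeric(0),
                                      n_sites = integer(0)))
  key <- paste(tiles$chrom, tiles$win_index)
  skey <- paste(stats$chrom, (stats$pos - 1) %/% window_bp + 1)
  idx <- match(skey, key)
  mean_by <- function(x) {
    s <- tapply(x, factor(idx, levels = seq_len(nrow(tiles))),
                function(v) mean(v, na.rm = TRUE))
    out <- as.vector(s, mode = "numeric")
    out[is.nan(out)] <- NA_real_
    out[is.na(s)] <- NA_real_
    out
  }
  tiles$mean_fst <- mean_by(stats$fst)
  tiles$mean_neglog10p <- mean_by(stats$neg_log10_p)
  cnt <- tapply(!is.na(stats$fisher_p),
                factor(idx, levels = seq_len(nrow(tiles))), sum)
  tiles$n_sites <- as.integer(ifelse(is.na(cnt), 0L, cnt))
  tiles
}

# window tiling shared by window_mean() and window_scan()
.window_tiles <- function(sites, window_bp, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    if (nrow(sites) == 0L) {
      return(data.frame(chrom = character(0), win_index = integer(0),
                        start = numeric(0), end = numeric(0)))
    }
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
    chrom_lengths <- chrom_lengths[unique(sites$chrom)]  # keep file order
  } else {
    unknown <- setdiff(unique(sites$chrom), names(chrom_lengths))
    if (length(unknown)) {
      stop("chromosome not in sequence dictionary: ",
           paste(unknown, collapse = ", "))
    }
  }
  nwin <- pmax(ceiling(chrom_lengths / window_bp), 0)
  chrom <- rep(names(nwin), nwin)
  win_index <- unlist(lapply(nwin, seq_len), use.names = FALSE)
  if (length(win_index) == 0L) win_index <- integer(0)
  data.frame(chrom = chrom, win_index = as.integer(win_index),
             start = (win_index - 1) * window_bp + 1,
             end = win_index * window_bp,
             stringsAsFactors = FALSE)
}

.check_sorted <- function(sites) {
  if (nrow(sites) < 2L) return(invisible(TRUE))
  same <- sites$chrom[-1L] == sites$chrom[-nrow(sites)]
  if (any(same & diff(sites$pos) <= 0)) {
    stop("input sites are not sorted by position within chromosome")
  }
  invisible(TRUE)
}
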