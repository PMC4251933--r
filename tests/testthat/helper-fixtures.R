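# In-code fixtures: compact constructors for sync tables and frequency
# tables used across the test files.

# build a pool_sync data frame from named base-count vectors, e.g.
# make_sync(pos = c(100, 200), m = list(c(A = 10), c(A = 5, T = 5)),
#           f = list(c(A = 12), c(A = 10)))
make_sync <- function(pos, m, f, chrom = "LG1", ref = "A") {
  fields <- c("A", "T", "C", "G", "N", "del")
  fill <- function(x) {
    v <- setNames(integer(6), fields)
    v[names(x)] <- as.integer(x)
    v
  }
  cm <- t(vapply(m, fill, integer(6)))
  cf <- t(vapply(f, fill, integer(6)))
  colnames(cm) <- paste0("m_", fields)
  colnames(cf) <- paste0("f_", fields)
  out <- data.frame(chrom = rep_len(chrom, length(pos)),
                    pos = as.integer(pos),
                    ref = rep_len(ref, length(pos)), cm, cf,
                    stringsAsFactors = FALSE)
  class(out) <- c("pool_sync", "data.frame")
  out
}

# frequency table straight from counts of a biallelic site set
make_freqs <- function(...) site_frequencies(make_sync(...))

# a synthetic window table from a vector of per-window counts
make_windows <- function(counts, chrom = "LG1", window_bp = 10000,
                         n_eligible = NULL) {
  n <- length(counts)
  out <- data.frame(chrom = rep_len(chrom, n), win_index = seq_len(n),
                    start = (seq_len(n) - 1) * window_bp + 1,
                    end = seq_len(n) * window_bp,
                    n_sex_snps = as.integer(counts),
                    n_eligible = if (is.null(n_eligible))
                      pmax(as.integer(counts), 1L) else as.integer(n_eligible))
  class(out) <- c("sexsnp_windows", "data.frame")
  out
}

region_row <- function(chrom = "LG1", start_bp, end_bp) {
  data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
             length_mb = (end_bp - start_bp + 1) / 1e6,
             stringsAsFactors = FALSE)
}

# small, fast simulation config for end-to-end tests: 5 Mb genome with a
# 1.5 Mb planted block
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(LG1 = 3e6, LG2 = 2e6),
             block_start = 1000001, block_end = 2500000,
             n_genes = 2000, n_genes_inside = 150, ...)
}
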