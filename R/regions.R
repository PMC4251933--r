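# Calling the differentiated block from the window track and the
# region-level density arithmetic.

#' Call differentiated blocks from a window track
#'
#' Finds maximal runs of windows whose sex-pattern SNP count reaches
#' `count_threshold`, bridging interior gaps of up to
#' `max_gap_windows` consecutive sub-threshold windows. Runs spanning
#' fewer than `min_run_windows` windows are dropped. Each surviving run
#' becomes a region spanning the first to the last window of the run.
#'
#' Defaults are tuned for a 10-kb window track at proto-Y-scale SNP
#' densities (thousands of qualifying SNPs per Mb inside the block,
#' tens outside): a block of several Mb is recovered while isolated
#' background windows are not called.
#'
#' @param windows A `sexsnp_windows` data frame from [window_scan()].
#' @param count_threshold Minimum `n_sex_snps` for a window to pass.
#' @param min_run_windows Minimum spanned length of a run, in windows.
#' @param max_gap_windows Maximum number of consecutive sub-threshold
#'   windows bridged inside a run.
#' @return Data frame with one row per called region: `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive), `length_mb`,
#'   `n_windows`. Empty (zero-row) when nothing passes.
#' @export
call_block <- function(windows, count_threshold = 5, min_run_windows = 50,
                       max_gap_windows = 20) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$win_index), , drop = FALSE]
    pass <- which(w$n_sex_snps >= count_threshold)
    if (length(pass) == 0L) next
    # cluster pass windows whose index gap leaves <= max_gap fails between
    brk <- c(TRUE, diff(w$win_index[pass]) > max_gap_windows + 1L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      first <- pass[which(grp == g)[1L]]
      last <- pass[which(grp == g)[sum(grp == g)]]
      span <- w$win_index[last] - w$win_index[first] + 1L
      if (span < min_run_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = w$start[first], end_bp = w$end[last],
        n_windows = span, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), length_mb = numeric(0),
                      n_windows = integer(0)))
  }
  res <- do.call(rbind, out)
  res$length_mb <- (res$end_bp - res$start_bp + 1) / 1e6
  res[c("chrom", "start_bp", "end_bp", "length_mb", "n_windows")]
}

#' Per-Mb SNP density of a region
#'
#' `density = n_snps / (region_length_bp / 1e6)`. Report to 3 decimals
#' when printing; the full-precision value is returned.
#'
#' @param n_snps Non-negative SNP count (vectorised).
#' @param region_length_bp Region length in bp (> 0; vectorised).
#' @return Numeric density in SNPs per Mb.
#' @export
region_density <- function(n_snps, region_length_bp) {
  if (any(region_length_bp <= 0)) stop("region length must be positive")
  if (any(n_snps < 0)) stop("SNP count must be non-negative")
  n_snps / (region_length_bp / 1e6)
}

#' Per-window count summaries inside vs outside a region
#'
#' Partitions windows by region membership (a window belongs to the
#' region when its midpoint lies inside) and reports the sample mean
#' and standard deviation (n - 1 denominator) of per-window sex-pattern
#' SNP counts on each side, optionally restricted to windows containing
#' at least one coverage-eligible position. With `k_top`, also reports
#' how many of the `k_top` highest-count windows fall inside the
#' region.
#'
#' @param windows A `sexsnp_windows` data frame.
#' @param region A one-row region (list or data frame with `chrom`,
#'   `start_bp`, `end_bp`), e.g. a row of [call_block()] output.
#' @param k_top Optional integer; report the top-`k_top` window overlap.
#' @param eligible_only If `TRUE`, restrict the mean/SD to windows with
#'   `n_eligible > 0`.
#' @return List with `mean_inside`, `sd_inside`, `mean_outside`,
#'   `sd_outside`, `n_windows_inside`, `n_windows_outside`, and (when
#'   `k_top` is given) `k_top` and `n_top_inside`. Empty partitions
#'   yield `NA`.
#' @export
window_count_summary <- function(windows, region, k_top = NULL,
                                 eligible_only = FALSE) {
  mid <- (windows$start + windows$end) / 2
  inside <- windows$chrom == region$chrom &
    mid >= region$start_bp & mid <= region$end_bp
  w <- windows
  keep <- if (eligible_only) w$n_eligible > 0 else rep(TRUE, nrow(w))
  msd <- function(x) {
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    c(mean(x), stats::sd(x))
  }
  ins <- msd(w$n_sex_snps[inside & keep])
  out <- msd(w$n_sex_snps[!inside & keep])
  res <- list(mean_inside = ins[1], sd_inside = ins[2],
              mean_outside = out[1], sd_outside = out[2],
              n_windows_inside = sum(inside & keep),
              n_windows_outside = sum(!inside & keep))
  if (!is.null(k_top)) {
    ord <- order(windows$n_sex_snps, decreasing = TRUE)
    top <- ord[seq_len(min(k_top, length(ord)))]
    res$k_top <- as.integer(k_top)
    res$n_top_inside <- sum(inside[top])
  }
  res
}

#' Write called regions as a BED file
#'
#' 0-based half-open intervals, one per region.
#'
#' @param regions Output of [call_block()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- if (nrow(regions)) {
    paste(regions$chrom,
          format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
          format(regions$end_bp, scientific = FALSE, trim = TRUE),
          sprintf("block_%d", seq_len(nrow(regions))), sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
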