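# End-to-end orchestration: sync -> frequencies -> site statistics ->
# sex-pattern windows -> called block -> effect and expression summaries.

#' Run the full proto-Y scan pipeline
#'
#' Takes a two-pool sync input (path or `pool_sync` data frame) and
#' optional effect-annotation and expression tables, and runs every
#' stage: per-site frequencies, F_ST and Fisher's exact statistics,
#' sex-pattern SNP classification, coverage-filtered window counts,
#' differentiated-block calling, per-Mb density arithmetic, effect-class
#' tallies, and the sex-biased expression enrichment test. All
#' thresholds default to the standard scan settings (intermediate band
#' `[0.3, 0.7]`, fixed band `<= 0.1` / `>= 0.9`, 10 reads minimum
#' coverage in each pool, 10-kb windows).
#'
#' @param sync Path to a sync file or a `pool_sync` data frame.
#' @param effects Optional path or data frame of effect annotations
#'   (see [read_effects()]).
#' @param expression Optional path or data frame of gene-model FPKMs
#'   (see [read_expression()]).
#' @param chrom_lengths Named vector of chromosome lengths; `NULL`
#'   infers each length from the last observed position.
#' @param polarity `"xy"` or `"zw"` (which pool is the intermediate
#'   one).
#' @param intermediate,fixed,min_cov Classifier thresholds, as in
#'   [classify_sex_snps()].
#' @param window_bp Window width for the scan.
#' @param count_threshold,min_run_windows,max_gap_windows Block-caller
#'   parameters, as in [call_block()].
#' @param genome_length_bp Total genome length used for outside-density
#'   denominators; defaults to `sum(chrom_lengths)` (or the inferred
#'   total).
#' @param min_fpkm,background Expression-test settings, as in
#'   [enrichment_report()].
#' @param pool_order Sync column order, as in [read_sync()].
#' @param compute_site_stats If `FALSE`, skip per-site F_ST/Fisher
#'   statistics (the sex-pattern scan does not need them).
#' @param out_dir Optional output directory for the TSV/IGV/BED/JSON
#'   report bundle.
#' @return An object of class `proto_y_scan` with elements `sites`
#'   (classified site table, with statistics when computed), `windows`,
#'   `regions`, `block` (the longest called region or `NULL`),
#'   `effect_summary`, `expression` (a `bias_enrichment`), `summary`
#'   (flat list of headline numbers) and `settings`.
#' @export
run_pipeline <- function(sync, effects = NULL, expression = NULL,
                         chrom_lengths = NULL,
                         polarity = c("xy", "zw"),
                         intermediate = c(0.3, 0.7), fixed = c(0.1, 0.9),
                         min_cov = 10, window_bp = 10000,
                         count_threshold = 5, min_run_windows = 50,
                         max_gap_windows = 20,
                         genome_length_bp = NULL,
                         min_fpkm = 0.05,
                         background = c("genomewide", "outside"),
                         pool_order = c("male", "female"),
                         compute_site_stats = TRUE,
                         out_dir = NULL) {
  polarity <- match.arg(polarity)
  background <- match.arg(background)
  if (is.character(sync)) sync <- read_sync(sync, pool_order = pool_order)
  if (is.character(effects)) effects <- read_effects(effects)
  if (is.character(expression)) expression <- read_expression(expression)

  freqs <- site_frequencies(sync)
  if (compute_site_stats) freqs <- site_stats(freqs)
  classified <- classify_sex_snps(freqs, intermediate = intermediate,
                                  fixed = fixed, min_cov = min_cov,
                                  polarity = polarity)
  windows <- window_scan(classified, chrom_lengths = chrom_lengths,
                         window_bp = window_bp)
  if (is.null(genome_length_bp)) {
    genome_length_bp <- if (is.null(chrom_lengths)) {
      sum(tapply(windows$end, windows$chrom, max))
    } else sum(chrom_lengths)
  }
  regions <- call_block(windows, count_threshold = count_threshold,
                        min_run_windows = min_run_windows,
                        max_gap_windows = max_gap_windows)
  block <- if (nrow(regions)) {
    regions[which.max(regions$length_mb), , drop = FALSE]
  } else NULL

  snps <- classified[classified$sex_pattern, , drop = FALSE]
  smry <- list(n_sites = nrow(classified),
               n_sex_pattern_snps = nrow(snps),
               n_regions = nrow(regions),
               genome_length_bp = genome_length_bp)
  effect_summary <- NULL
  expr_report <- NULL

  if (!is.null(block)) {
    inside <- snps$chrom == block$chrom & snps$pos >= block$start_bp &
      snps$pos <= block$end_bp
    block_len <- block$end_bp - block$start_bp + 1
    wsum <- window_count_summary(windows, block, k_top = 300)
    smry <- c(smry, list(
      block_chrom = block$chrom,
      block_start_bp = block$start_bp, block_end_bp = block$end_bp,
      block_length_mb = block$length_mb,
      n_snps_inside = sum(inside), n_snps_outside = sum(!inside),
      density_inside_per_mb = region_density(sum(inside), block_len),
      density_outside_per_mb = region_density(sum(!inside),
                                              genome_length_bp - block_len),
      mean_snps_per_window_inside = wsum$mean_inside,
      sd_snps_per_window_inside = wsum$sd_inside,
      mean_snps_per_window_outside = wsum$mean_outside,
      sd_snps_per_window_outside = wsum$sd_outside,
      n_top300_windows_inside = wsum$n_top_inside))
    if (!is.null(effects)) {
      effect_summary <- summarize_effects(effects, snps, block,
                                          genome_length_bp)
    }
    if (!is.null(expression)) {
      expr_report <- enrichment_report(expression, block,
                                       min_fpkm = min_fpkm,
                                       background = background)
      smry <- c(smry, list(
        expr_male_inside = expr_report$male_in,
        expr_female_inside = expr_report$female_in,
        expr_chi2 = expr_report$chi2, expr_p = expr_report$p))
    }
  }

  res <- structure(list(
    sites = classified, windows = windows, regions = regions,
    block = block, effect_summary = effect_summary,
    expression = expr_report, summary = smry,
    settings = list(polarity = polarity, intermediate = intermediate,
                    fixed = fixed, min_cov = min_cov,
                    window_bp = window_bp,
                    count_threshold = count_threshold,
                    min_run_windows = min_run_windows,
                    max_gap_windows = max_gap_windows,
                    genome_length_bp = genome_length_bp,
                    min_fpkm = min_fpkm, background = background)),
    class = "proto_y_scan")
  if (!is.null(out_dir)) .write_bundle(res, out_dir)
  res
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  site_cols <- intersect(c("chrom", "pos", "fst", "fisher_p", "neg_log10_p"),
                         names(res$sites))
  if (all(c("fst", "fisher_p") %in% site_cols)) {
    tsv(res$sites[site_cols], "site_stats.tsv")
  }
  tsv(res$windows, "windows.tsv")
  write_igv_track(res$windows, file.path(out_dir, "windows.igv"))
  snps <- res$sites[res$sites$sex_pattern, , drop = FALSE]
  write_igv_track(snps, file.path(out_dir, "sex_snps.igv"))
  write_regions_bed(res$regions, file.path(out_dir, "regions.bed"))
  if (!is.null(res$effect_summary)) tsv(res$effect_summary,
                                        "effect_summary.tsv")
  if (!is.null(res$expression)) {
    e <- res$expression
    tsv(e$genes[e$genes$bias %in% c("male", "female"), , drop = FALSE],
        "expression_bias.tsv")
  }
  jsonlite::write_json(c(res$summary, res$settings),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.proto_y_scan <- function(x, ...) {
  s <- x$summary
  cat("Proto-Y pool-seq scan\n")
  cat(sprintf("  %d sites, %d sex-pattern SNPs, %d region(s) called\n",
              s$n_sites, s$n_sex_pattern_snps, s$n_regions))
  if (!is.null(x$block)) {
    cat(sprintf("  block: %s:%.0f-%.0f (%.2f Mb)\n", s$block_chrom,
                s$block_start_bp, s$block_end_bp, s$block_length_mb))
    cat(sprintf("  SNP density: %.3f/Mb inside vs %.3f/Mb outside\n",
                s$density_inside_per_mb, s$density_outside_per_mb))
  } else {
    cat("  no differentiated block called\n")
  }
  if (!is.null(x$expression) && !is.na(x$expression$chi2)) {
    cat(sprintf("  expression: %d male- vs %d female-biased inside, chi2 = %.2f (p = %.3g)\n",
                x$expression$male_in, x$expression$female_in,
                x$expression$chi2, x$expression$p))
  }
  invisible(x)
}

#' @export
summary.proto_y_scan <- function(object, ...) {
  object$summary
}

#' Plot the sex-pattern SNP window track
#'
#' One panel per chromosome: per-window qualifying-SNP counts, with any
#' called regions shaded.
#'
#' @param x A `proto_y_scan` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.proto_y_scan <- function(x, ...) {
  chroms <- unique(x$windows$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    w <- x$windows[x$windows$chrom == ch, ]
    graphics::plot((w$start + w$end) / 2e6, w$n_sex_snps, type = "h",
                   xlab = paste(ch, "position (Mb)"),
                   ylab = "sex-pattern SNPs / window", main = ch, ...)
    r <- x$regions[x$regions$chrom == ch, ]
    if (nrow(r)) {
      graphics::rect(r$start_bp / 1e6, 0, r$end_bp / 1e6,
                     max(w$n_sex_snps),
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  invisible(x)
}
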