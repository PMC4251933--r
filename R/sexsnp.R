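# Sex-pattern SNP classification: sites at intermediate frequency in the
# heterogametic-sex pool and fixed or nearly fixed in the other pool,
# counted in coverage-filtered non-overlapping windows.

#' Classify sex-pattern SNPs
#'
#' A site qualifies when the *same* pooled minor allele sits at
#' intermediate frequency (default `[0.3, 0.7]`, bounds inclusive) in
#' the intermediate pool and is fixed or nearly fixed (default
#' frequency `<= 0.1` or `>= 0.9`, bounds inclusive) in the other pool
#' — the signature of a Y-specific (or, with `polarity = "zw"`,
#' W-specific) allele. Under `polarity = "xy"` the male pool is the
#' intermediate pool. Only positions with coverage of at least
#' `min_cov` reads in *each* pool are eligible.
#'
#' @param freqs A `site_freqs` data frame from [site_frequencies()].
#' @param intermediate Length-2 numeric, the inclusive intermediate
#'   frequency band.
#' @param fixed Length-2 numeric `c(lo, hi)`: fixed/nearly fixed means
#'   frequency `<= lo` or `>= hi`, inclusive.
#' @param min_cov Minimum A/T/C/G coverage required in each pool.
#' @param polarity `"xy"` (male pool intermediate; default) or `"zw"`
#'   (female pool intermediate).
#' @return The input data frame with logical columns `eligible`
#'   (coverage filter) and `sex_pattern` (qualifying SNP) appended.
#' @export
classify_sex_snps <- function(freqs, intermediate = c(0.3, 0.7),
                              fixed = c(0.1, 0.9), min_cov = 10,
                              polarity = c("xy", "zw")) {
  polarity <- match.arg(polarity)
  if (length(intermediate) != 2L || intermediate[1] > intermediate[2]) {
    stop("intermediate must be c(lo, hi) with lo <= hi")
  }
  if (length(fixed) != 2L || fixed[1] > fixed[2]) {
    stop("fixed must be c(lo, hi) with lo <= hi")
  }
  f_int <- if (polarity == "xy") freqs$f_male else freqs$f_female
  f_fix <- if (polarity == "xy") freqs$f_female else freqs$f_male
  eligible <- freqs$cov_male >= min_cov & freqs$cov_female >= min_cov &
    !freqs$uncomputable
  qual <- eligible & !is.na(f_int) & !is.na(f_fix) &
    f_int >= intermediate[1] & f_int <= intermediate[2] &
    (f_fix <= fixed[1] | f_fix >= fixed[2])
  freqs$eligible <- eligible
  freqs$sex_pattern <- qual
  freqs
}

#' Count sex-pattern SNPs in non-overlapping windows
#'
#' Tiles every chromosome of the sequence dictionary with
#' non-overlapping windows of `window_bp` and counts qualifying SNPs
#' per window. Positions failing the coverage filter are excluded; each
#' window also reports how many eligible positions it contains (among
#' the positions present in the input — for a variants-only sync file
#' this counts variant sites, not every base).
#'
#' @param classified A data frame from [classify_sex_snps()].
#' @param chrom_lengths Optional named numeric vector of chromosome
#'   lengths; when `NULL`, each chromosome is tiled up to its last
#'   observed position. Sites on chromosomes absent from the dictionary
#'   raise an error naming the chromosome.
#' @param window_bp Window width in bp (default 10 kb).
#' @return Data frame of class `sexsnp_windows` with columns `chrom`,
#'   `win_index`, `start`, `end` (1-based inclusive), `n_sex_snps`,
#'   `n_eligible`.
#' @export
window_scan <- function(classified, chrom_lengths = NULL, window_bp = 10000) {
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp <= 0) {
    stop("window_bp must be a single positive number")
  }
  if (is.null(classified$sex_pattern)) {
    stop("input must come from classify_sex_snps()")
  }
  .check_sorted(classified)
  tiles <- .window_tiles(classified, window_bp, chrom_lengths)
  key <- paste(tiles$chrom, tiles$win_index)
  skey <- paste(classified$chrom, (classified$pos - 1) %/% window_bp + 1)
  idx <- factor(match(skey, key), levels = seq_len(nrow(tiles)))
  count_of <- function(x) {
    s <- tapply(x, idx, sum)
    as.integer(ifelse(is.na(s), 0L, s))
  }
  tiles$n_sex_snps <- count_of(classified$sex_pattern)
  tiles$n_eligible <- count_of(classified$eligible)
  class(tiles) <- c("sexsnp_windows", "data.frame")
  tiles
}

#' Write an IGV track of SNPs or window counts
#'
#' Writes a tab-delimited `.igv` track (`Chromosome`, `Start`, `End`,
#' `Feature`, value). Starts are 0-based half-open, as IGV expects; the
#' conversion from the package's 1-based inclusive coordinates is noted
#' in the file's comment header. A window table writes one row per
#' window with its SNP count; a site table writes one row per
#' qualifying SNP.
#'
#' @param x Either a `sexsnp_windows` data frame from [window_scan()]
#'   or a classified site table from [classify_sex_snps()] (only rows
#'   with `sex_pattern == TRUE` are written).
#' @param path Output file path.
#' @param feature Feature label for the track's fourth column.
#' @return `path`, invisibly.
#' @export
write_igv_track <- function(x, path, feature = "sex_snp") {
  if (!is.null(x$n_sex_snps)) {
    rows <- data.frame(Chromosome = x$chrom, Start = x$start - 1,
                       End = x$end,
                       Feature = rep_len(feature, nrow(x)),
                       value = x$n_sex_snps)
    value_name <- "n_sex_snps"
  } else if (!is.null(x$sex_pattern)) {
    s <- x[x$sex_pattern, , drop = FALSE]
    rows <- data.frame(Chromosome = s$chrom, Start = s$pos - 1,
                       End = s$pos, Feature = rep_len(feature, nrow(s)),
                       value = round(s$f_male - s$f_female, 6))
    value_name <- "freq_diff"
  } else {
    stop("x must be a window table or a classified site table")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#coordinates: 0-based half-open (Start = 1-based position - 1)",
               paste("Chromosome", "Start", "End", "Feature", value_name,
                     sep = "\t")), con)
  if (nrow(rows)) {
    writeLines(paste(rows$Chromosome, format(rows$Start, scientific = FALSE,
                                             trim = TRUE),
                     format(rows$End, scientific = FALSE, trim = TRUE),
                     rows$Feature, rows$value, sep = "\t"), con)
  }
  invisible(path)
}
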