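# Variant effect-class summaries: intersect sex-pattern SNPs with an
# effect-annotation table and tally classes inside/outside the block.

.EFFECT_CLASSES <- c("STOP_GAIN", "STOP_LOST", "START_LOST", "SPLICE_SITE",
                     "NON_SYNONYMOUS", "OTHER")

# fixed dictionary mapping SnpEff-style terms onto the closed vocabulary
.SNPEFF_MAP <- c(
  STOP_GAINED = "STOP_GAIN", STOP_GAIN = "STOP_GAIN",
  STOP_LOST = "STOP_LOST",
  START_LOST = "START_LOST", START_LOSS = "START_LOST",
  SPLICE_SITE = "SPLICE_SITE",
  SPLICE_SITE_ACCEPTOR = "SPLICE_SITE", SPLICE_SITE_DONOR = "SPLICE_SITE",
  SPLICE_ACCEPTOR_VARIANT = "SPLICE_SITE", SPLICE_DONOR_VARIANT = "SPLICE_SITE",
  NON_SYNONYMOUS = "NON_SYNONYMOUS",
  NON_SYNONYMOUS_CODING = "NON_SYNONYMOUS",
  MISSENSE_VARIANT = "NON_SYNONYMOUS",
  OTHER = "OTHER")

#' Read a variant effect-annotation table
#'
#' Expects a tab-delimited file with a header containing at least
#' `chrom`, `pos`, `gene` and `effect_class` (optionally `ref_codon`,
#' `alt_codon`). Effect terms are mapped onto the closed vocabulary
#' `STOP_GAIN, STOP_LOST, START_LOST, SPLICE_SITE, NON_SYNONYMOUS,
#' OTHER` through a fixed SnpEff-style dictionary; unknown terms map to
#' `OTHER` with a warning. Duplicate (site, gene, class) rows are
#' dropped with a warning.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `chrom`, `pos`, `gene`,
#'   `effect_class` (factor over the closed vocabulary) plus any codon
#'   columns present.
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) stop("effects table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gene", "effect_class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("effects table is missing column(s): ", paste(miss, collapse = ", "))
  }
  raw <- toupper(tab$effect_class)
  mapped <- unname(.SNPEFF_MAP[raw])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning("unknown effect class(es) mapped to OTHER: ",
            paste(unique(raw[unknown]), collapse = ", "))
    mapped[unknown] <- "OTHER"
  }
  tab$effect_class <- factor(mapped, levels = .EFFECT_CLASSES)
  dup <- duplicated(tab[c("chrom", "pos", "gene", "effect_class")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (site, gene, class) row(s) removed")
    tab <- tab[!dup, , drop = FALSE]
  }
  tab
}

#' Tally effect classes inside and outside a region
#'
#' Restricts the annotation table to sites that are qualifying
#' sex-pattern SNPs, then counts each effect class inside and outside
#' the region and converts counts to per-Mb densities. The outside
#' denominator is the genome length minus the region length. A pooled
#' `STOP_CHANGE` row (stop gains + stop losses) is appended, since stop
#' codon changes of either direction disrupt the coding sequence.
#'
#' @param annotations Data frame from [read_effects()].
#' @param sex_snps Data frame with `chrom` and `pos` of qualifying
#'   sex-pattern SNPs (e.g. the `sex_pattern` rows of
#'   [classify_sex_snps()] output).
#' @param region One-row region (`chrom`, `start_bp`, `end_bp`).
#' @param genome_length_bp Total genome length in bp; must exceed the
#'   region length.
#' @return Data frame with `effect_class`, `n_inside`, `n_outside`,
#'   `density_inside`, `density_outside` (per Mb).
#' @export
summarize_effects <- function(annotations, sex_snps, region,
                              genome_length_bp) {
  region_len <- region$end_bp - region$start_bp + 1
  if (region_len >= genome_length_bp) {
    stop("region length must be smaller than the genome length")
  }
  qual_key <- paste(sex_snps$chrom, sex_snps$pos)
  keep <- paste(annotations$chrom, annotations$pos) %in% qual_key
  ann <- annotations[keep, , drop = FALSE]
  inside <- ann$chrom == region$chrom &
    ann$pos >= region$start_bp & ann$pos <= region$end_bp
  cls <- factor(ann$effect_class, levels = .EFFECT_CLASSES)
  n_in <- as.integer(table(cls[inside]))
  n_out <- as.integer(table(cls[!inside]))
  res <- data.frame(effect_class = .EFFECT_CLASSES,
                    n_inside = n_in, n_outside = n_out,
                    stringsAsFactors = FALSE)
  stop_row <- data.frame(effect_class = "STOP_CHANGE",
                         n_inside = sum(n_in[1:2]),
                         n_outside = sum(n_out[1:2]))
  res <- rbind(res, stop_row)
  res$density_inside <- region_density(res$n_inside, region_len)
  res$density_outside <- region_density(res$n_outside,
                                        genome_length_bp - region_len)
  res
}
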