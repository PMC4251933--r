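# Sex-biased expression: classify gene models from per-sex FPKM and test
# enrichment of female-biased models inside the differentiated block.

#' Classify expression bias from per-sex FPKM
#'
#' A gene model is `excluded` when its FPKM is below `min_fpkm` in
#' *both* sexes; otherwise it is assigned to the sex with the larger
#' FPKM. The case where one sex expresses (FPKM above threshold) and
#' the other has zero FPKM counts as biased toward the expressing sex.
#' Equal non-excluded FPKMs are a `tie`, counted in neither class.
#'
#' @param fpkm_male,fpkm_female Non-negative FPKM vectors.
#' @param min_fpkm Exclusion threshold (default 0.05).
#' @return Character vector over `male`, `female`, `tie`, `excluded`.
#' @export
classify_bias <- function(fpkm_male, fpkm_female, min_fpkm = 0.05) {
  if (any(!is.finite(fpkm_male)) || any(!is.finite(fpkm_female)) ||
      any(fpkm_male < 0) || any(fpkm_female < 0)) {
    stop("FPKM values must be finite and non-negative")
  }
  out <- ifelse(fpkm_male < min_fpkm & fpkm_female < min_fpkm, "excluded",
         ifelse(fpkm_male > fpkm_female, "male",
         ifelse(fpkm_female > fpkm_male, "female", "tie")))
  out
}

#' Yates-corrected chi-square on a 2x2 table
#'
#' \deqn{\chi^2 = \sum \frac{\max(|O - E| - 0.5,\, 0)^2}{E}} over the
#' four cells, with the truncation at zero so that perfectly
#' proportional tables score exactly 0. The p-value is the upper tail
#' of the chi-square distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Cell counts, row-wise (`a`,`b` top row).
#' @return List with `chi2` and `p`.
#' @export
yates_chi2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(o < 0)) stop("cell counts must be non-negative")
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2 <- sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Read a gene-model expression table
#'
#' Tab-delimited with header columns `gene_id`, `chrom`, `start`,
#' `end`, `fpkm_male`, `fpkm_female` (coordinates 1-based inclusive).
#'
#' @param path Path to the TSV.
#' @return Data frame with those columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "fpkm_male", "fpkm_female")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("expression table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' Enrichment of sex-biased gene models inside a region
#'
#' Classifies every gene model with [classify_bias()], assigns genes to
#' the region by midpoint, and tests whether the male/female bias
#' composition inside the region differs from the background with a
#' Yates-corrected chi-square on the 2x2 table
#' \{inside, background\} x \{male-biased, female-biased\}. The
#' background is the genome-wide classified set by default (which
#' includes the region) or, with `background = "outside"`, the
#' complement of the region.
#'
#' @param records Expression table as from [read_expression()].
#' @param region One-row region (`chrom`, `start_bp`, `end_bp`).
#' @param min_fpkm Exclusion threshold passed to [classify_bias()].
#' @param background `"genomewide"` (default) or `"outside"`.
#' @return Object of class `bias_enrichment`: counts (`male_in`,
#'   `female_in`, `male_bg`, `female_bg`, plus genome-wide totals, ties
#'   and exclusions), percentages, `chi2`, `p`, the per-gene table with
#'   `bias`, `inside` and `log2_ratio` (log2 male/female FPKM) columns,
#'   and the options used. When the region contains no classified gene
#'   model the test is `NA`.
#' @export
enrichment_report <- function(records, region, min_fpkm = 0.05,
                              background = c("genomewide", "outside")) {
  background <- match.arg(background)
  bias <- classify_bias(records$fpkm_male, records$fpkm_female, min_fpkm)
  mid <- (records$start + records$end) / 2
  inside <- records$chrom == region$chrom &
    mid >= region$start_bp & mid <= region$end_bp

  male_in <- sum(bias == "male" & inside)
  female_in <- sum(bias == "female" & inside)
  male_all <- sum(bias == "male")
  female_all <- sum(bias == "female")
  male_bg <- if (background == "genomewide") male_all else male_all - male_in
  female_bg <- if (background == "genomewide") female_all else
    female_all - female_in

  test <- if ((male_in + female_in) == 0 || (male_bg + female_bg) == 0 ||
              (male_in + male_bg) == 0 || (female_in + female_bg) == 0) {
    list(chi2 = NA_real_, p = NA_real_)
  } else {
    yates_chi2(male_in, female_in, male_bg, female_bg)
  }

  genes <- records
  genes$bias <- bias
  genes$inside <- inside
  genes$log2_ratio <- log2(genes$fpkm_male / genes$fpkm_female)

  structure(list(
    male_in = male_in, female_in = female_in,
    male_bg = male_bg, female_bg = female_bg,
    male_all = male_all, female_all = female_all,
    n_ties = sum(bias == "tie"), n_excluded = sum(bias == "excluded"),
    n_models = nrow(records),
    pct_male_in = 100 * male_in / max(male_in + female_in, 1L),
    pct_female_in = 100 * female_in / max(male_in + female_in, 1L),
    chi2 = test$chi2, p = test$p,
    background = background, min_fpkm = min_fpkm,
    genes = genes), class = "bias_enrichment")
}

#' @export
print.bias_enrichment <- function(x, ...) {
  cat("Sex-biased expression enrichment\n")
  cat(sprintf("  inside region: %d male-biased, %d female-biased (%.1f%% female)\n",
              x$male_in, x$female_in, x$pct_female_in))
  cat(sprintf("  background (%s): %d male-biased, %d female-biased\n",
              x$background, x$male_bg, x$female_bg))
  cat(sprintf("  ties: %d, excluded (FPKM < %.2g in both sexes): %d\n",
              x$n_ties, x$min_fpkm, x$n_excluded))
  if (is.na(x$chi2)) {
    cat("  chi-square test: not computable (degenerate table)\n")
  } else {
    cat(sprintf("  Yates chi-square = %.2f, p = %.4g\n", x$chi2, x$p))
  }
  invisible(x)
}
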