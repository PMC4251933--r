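# Synthetic proto-Y pool-seq generator: sync files, effect tables,
# expression tables and truth, with the statistical structure the scan
# assumes (an XY block where Y-specific alleles sit at frequency 0.5 in
# the male pool and ~0 in the female pool, over shared background
# polymorphism).

#' Simulation configuration
#'
#' Defaults emulate a family-pooled XY design: two 40-Mb chromosomes
#' with an 8.8-Mb differentiated block at 10.1-18.9 Mb on LG1, pools of
#' 58 males and 33 females, mean per-pool coverages of 33 (male) and 37
#' (female) reads, Y-specific fixed differences at 2e-3 per bp inside
#' the block, shared background polymorphism at 2.5e-5 per bp, and a
#' sequencing error rate of 0.002 per read. Expression defaults place
#' 234 of 22,411 gene models inside the block with 69% female-biased
#' models inside versus 60% elsewhere.
#'
#' @param seed Integer RNG seed.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param block_chrom,block_start,block_end The planted block (1-based
#'   inclusive; must lie within its chromosome).
#' @param n_males,n_females Pool sizes (individuals).
#' @param cov_male,cov_female Mean per-site read coverages (Poisson
#'   means, or negative-binomial means when `overdispersion` is set).
#' @param rho_xy Per-bp rate of Y-specific fixed-difference sites
#'   inside the block.
#' @param rho_bg Per-bp rate of background polymorphic sites
#'   (genome-wide, frequency shared between the sexes).
#' @param error_rate Per-read error rate.
#' @param x_polymorphism Alt-allele frequency on the X at planted XY
#'   sites (0 = fully fixed females).
#' @param overdispersion Optional negative-binomial size parameter for
#'   coverages; `NULL` (default) uses Poisson coverage.
#' @param n_genes,n_genes_inside Total gene models and the number
#'   placed inside the block.
#' @param p_excluded Fraction of gene models with FPKM below the
#'   exclusion threshold in both sexes.
#' @param frac_female_inside,frac_female_genome Fraction of classified
#'   gene models that are female-biased inside the block / elsewhere.
#' @param p_zero_low Probability that the lower-expressed sex has FPKM
#'   exactly 0 (exercises the zero-vs-expressed bias rule).
#' @param effect_probs Named per-site probabilities that a simulated
#'   variant carries each annotated effect class (remainder
#'   unannotated).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(LG1 = 40e6, LG2 = 40e6),
                       block_chrom = "LG1",
                       block_start = 10100001, block_end = 18900000,
                       n_males = 58, n_females = 33,
                       cov_male = 33, cov_female = 37,
                       rho_xy = 2e-3, rho_bg = 2.5e-5,
                       error_rate = 0.002, x_polymorphism = 0,
                       overdispersion = NULL,
                       n_genes = 22411, n_genes_inside = 234,
                       p_excluded = 0.047,
                       frac_female_inside = 0.69,
                       frac_female_genome = 0.60,
                       p_zero_low = 0.05,
                       effect_probs = c(NON_SYNONYMOUS = 9.2e-3,
                                        STOP_GAIN = 5.5e-4,
                                        STOP_LOST = 1.6e-4,
                                        START_LOST = 1.6e-4,
                                        SPLICE_SITE = 1.1e-4,
                                        OTHER = 0.02)) {
  cfg <- as.list(environment())
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (!block_chrom %in% names(chrom_lengths)) {
    stop("block chromosome not in chrom_lengths")
  }
  if (block_start < 1 || block_end > chrom_lengths[[block_chrom]] ||
      block_start > block_end) {
    stop("block interval must lie within its chromosome")
  }
  rates <- c(rho_xy, rho_bg, error_rate, x_polymorphism, p_excluded,
             frac_female_inside, frac_female_genome, p_zero_low)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_males < 1 || n_females < 1) stop("pool sizes must be >= 1")
  if (sum(effect_probs) > 1) stop("effect_probs must sum to at most 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate pool read counts at Y-specific fixed-difference sites
#'
#' At an XY fixed-difference site the Y allele sits at chromosome
#' frequency 0.5 in the male pool (every male is X/Y) and
#' `x_polymorphism` (default 0) in the female pool. With per-read
#' error rate `e` and true alt frequency `f`, alt read counts are
#' Binomial(coverage, `f (1 - e) + (1 - f) e`).
#'
#' @param cov_male,cov_female Integer coverage vectors (recycled to a
#'   common length).
#' @param error_rate Per-read error rate.
#' @param x_polymorphism Female-pool alt frequency.
#' @return Data frame with `cov_male`, `cov_female`, `alt_male`,
#'   `alt_female`.
#' @export
simulate_site_xy <- function(cov_male, cov_female, error_rate = 0.002,
                             x_polymorphism = 0) {
  n <- max(length(cov_male), length(cov_female))
  cov_male <- rep_len(cov_male, n)
  cov_female <- rep_len(cov_female, n)
  p_m <- 0.5 * (1 - error_rate) + 0.5 * error_rate
  p_f <- x_polymorphism * (1 - error_rate) + (1 - x_polymorphism) * error_rate
  data.frame(cov_male = cov_male, cov_female = cov_female,
             alt_male = stats::rbinom(n, cov_male, p_m),
             alt_female = stats::rbinom(n, cov_female, p_f))
}

.sim_coverage <- function(n, mean_cov, overdispersion) {
  if (is.null(overdispersion)) {
    stats::rpois(n, mean_cov)
  } else {
    stats::rnbinom(n, size = overdispersion, mu = mean_cov)
  }
}

# variant sites (positions, classes, per-pool counts) for one config
.sim_sites <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  pos_l <- list(); chrom_l <- list(); class_l <- list()
  for (ch in chroms) {
    L <- cfg$chrom_lengths[[ch]]
    n_bg <- stats::rpois(1L, L * cfg$rho_bg)
    p_bg <- if (n_bg > 0) sample.int(L, n_bg) else integer(0)
    p_xy <- integer(0)
    if (ch == cfg$block_chrom && cfg$rho_xy > 0) {
      bl <- cfg$block_end - cfg$block_start + 1
      n_xy <- stats::rpois(1L, bl * cfg$rho_xy)
      if (n_xy > 0) p_xy <- cfg$block_start - 1L + sample.int(bl, n_xy)
    }
    p_bg <- setdiff(p_bg, p_xy)
    pos <- c(p_xy, p_bg)
    cls <- c(rep("XY_fixed_diff", length(p_xy)),
             rep("background", length(p_bg)))
    o <- order(pos)
    pos_l[[ch]] <- pos[o]; class_l[[ch]] <- cls[o]
    chrom_l[[ch]] <- rep(ch, length(pos))
  }
  pos <- unlist(pos_l, use.names = FALSE)
  n <- length(pos)
  sites <- data.frame(chrom = unlist(chrom_l, use.names = FALSE),
                      pos = as.integer(pos),
                      class = unlist(class_l, use.names = FALSE),
                      stringsAsFactors = FALSE)

  cov_m <- .sim_coverage(n, cfg$cov_male, cfg$overdispersion)
  cov_f <- .sim_coverage(n, cfg$cov_female, cfg$overdispersion)
  is_xy <- sites$class == "XY_fixed_diff"
  f_bg <- stats::runif(n, 0.05, 0.95)
  f_m <- ifelse(is_xy, 0.5, f_bg)
  f_f <- ifelse(is_xy, cfg$x_polymorphism, f_bg)
  e <- cfg$error_rate
  alt_m <- stats::rbinom(n, cov_m, f_m * (1 - e) + (1 - f_m) * e)
  alt_f <- stats::rbinom(n, cov_f, f_f * (1 - e) + (1 - f_f) * e)

  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), character(1))
  cm <- matrix(0L, n, 6L, dimnames = list(NULL, paste0("m_", .SYNC_FIELDS)))
  cfm <- matrix(0L, n, 6L, dimnames = list(NULL, paste0("f_", .SYNC_FIELDS)))
  ri <- match(ref, .SYNC_FIELDS); ai <- match(alt, .SYNC_FIELDS)
  cm[cbind(seq_len(n), ri)] <- cov_m - alt_m
  cm[cbind(seq_len(n), ai)] <- alt_m
  cfm[cbind(seq_len(n), ri)] <- cov_f - alt_f
  cfm[cbind(seq_len(n), ai)] <- alt_f

  sync <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                     cm, cfm, stringsAsFactors = FALSE)
  class(sync) <- c("pool_sync", "data.frame")
  list(sync = sync, sites = sites,
       freqs = data.frame(f_male_true = f_m, f_female_true = f_f,
                          alt_male = alt_m, alt_female = alt_f,
                          cov_male = cov_m, cov_female = cov_f))
}

# annotate simulated variant sites with effect classes
.sim_effects <- function(cfg, sites, freqs) {
  n <- nrow(sites)
  classes <- names(cfg$effect_probs)
  p <- c(cfg$effect_probs, NONE = 1 - sum(cfg$effect_probs))
  draw <- sample(names(p), n, replace = TRUE, prob = p)
  keep <- draw != "NONE"
  if (!any(keep)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      gene = character(0), effect_class = character(0),
                      ref_codon = character(0), alt_codon = character(0),
                      f_male = numeric(0), f_female = numeric(0)))
  }
  k <- which(keep)
  data.frame(chrom = sites$chrom[k], pos = sites$pos[k],
             gene = sprintf("gene_%s_%06d", sites$chrom[k],
                            sites$pos[k] %/% 50000L),
             effect_class = draw[k],
             ref_codon = ".", alt_codon = ".",
             f_male = round(freqs$alt_male[k] /
                              pmax(freqs$cov_male[k], 1L), 4),
             f_female = round(freqs$alt_female[k] /
                                pmax(freqs$cov_female[k], 1L), 4),
             stringsAsFactors = FALSE)
}

#' Simulate a gene-model expression table
#'
#' Places `n_genes_inside` gene models inside the block and the rest
#' uniformly across the remainder of the genome, assigns each a true
#' bias (female with probability `frac_female_inside` inside the block,
#' `frac_female_genome` elsewhere; `excluded` with probability
#' `p_excluded`), and draws log-normal FPKMs consistent with that bias.
#' With probability `p_zero_low` the lower-expressed sex gets FPKM 0.
#' Uses the current RNG state unless `seed` is given.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return List with `expression` (gene table as in
#'   [read_expression()]) and `truth` (per-gene true bias).
#' @export
simulate_expression <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_genes
  n_in <- cfg$n_genes_inside
  if (n_in > n) stop("n_genes_inside exceeds n_genes")
  block_len <- cfg$block_end - cfg$block_start + 1
  total_len <- sum(cfg$chrom_lengths)

  mid_in <- cfg$block_start - 1 + sample.int(block_len, n_in, replace = TRUE)
  chrom_in <- rep(cfg$block_chrom, n_in)
  # outside genes: uniform over the genome minus the block, by mapping a
  # uniform draw on the reduced length back onto coordinates
  n_out <- n - n_in
  u <- sample(total_len - block_len, n_out, replace = TRUE)
  bounds <- cumsum(cfg$chrom_lengths)
  offs <- c(0, bounds[-length(bounds)])
  blk_off <- offs[[match(cfg$block_chrom, names(cfg$chrom_lengths))]]
  g0 <- ifelse(u > blk_off + cfg$block_start - 1, u + block_len, u)
  ci <- findInterval(g0 - 1, c(0, bounds), rightmost.closed = FALSE)
  chrom_out <- names(cfg$chrom_lengths)[ci]
  mid_out <- g0 - offs[ci]

  chrom <- c(chrom_in, chrom_out)
  mid <- c(mid_in, mid_out)
  inside <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  width <- round(stats::runif(n, 2000, 20000))
  start <- pmax(1, round(mid - width / 2))
  end <- start + width - 1

  excl <- stats::runif(n) < cfg$p_excluded
  p_fem <- ifelse(inside, cfg$frac_female_inside, cfg$frac_female_genome)
  fem <- stats::runif(n) < p_fem
  bias <- ifelse(excl, "excluded", ifelse(fem, "female", "male"))

  hi <- exp(stats::rnorm(n, 1, 1.2)) + 0.05
  lo <- hi * stats::runif(n, 0.05, 0.95)
  lo[stats::runif(n) < cfg$p_zero_low] <- 0
  fpkm_m <- ifelse(bias == "male", hi, lo)
  fpkm_f <- ifelse(bias == "female", hi, lo)
  both_low <- stats::runif(n, 0, 0.049)
  fpkm_m[excl] <- both_low[excl]
  fpkm_f[excl] <- stats::runif(sum(excl), 0, 0.049)

  o <- order(match(chrom, names(cfg$chrom_lengths)), start)
  expr <- data.frame(gene_id = sprintf("model_%05d", seq_len(n)),
                     chrom = chrom, start = start, end = end,
                     fpkm_male = round(fpkm_m, 6),
                     fpkm_female = round(fpkm_f, 6),
                     stringsAsFactors = FALSE)[o, ]
  rownames(expr) <- NULL
  truth <- data.frame(gene_id = expr$gene_id,
                      true_bias = bias[o], inside_block = inside[o],
                      stringsAsFactors = FALSE)
  list(expression = expr, truth = truth)
}

#' Simulate a complete proto-Y pool-seq study
#'
#' Generates, deterministically for a given seed, a variants-only sync
#' table, an effect-annotation table, a gene-model expression table and
#' a truth record (planted block, per-site classes, per-gene bias).
#' Only variant positions are emitted (sparse emission), which keeps an
#' 80-Mb genome desk-scale.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, writes `pools.sync`,
#'   `effects.tsv`, `expression.tsv` and `truth.json` there.
#' @return A list of class `proto_y_sim` with elements `sync`, `sites`
#'   (truth classes), `effects`, `expression`, `gene_truth`, `config`
#'   and (if written) `paths`.
#' @export
simulate_genome <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  sim <- .sim_sites(cfg)
  effects <- .sim_effects(cfg, sim$sites, sim$freqs)
  expr <- simulate_expression(cfg)
  out <- list(sync = sim$sync, sites = sim$sites, effects = effects,
              expression = expr$expression, gene_truth = expr$truth,
              config = cfg)
  class(out) <- "proto_y_sim"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(sync = file.path(out_dir, "pools.sync"),
                  effects = file.path(out_dir, "effects.tsv"),
                  expression = file.path(out_dir, "expression.tsv"),
                  truth = file.path(out_dir, "truth.json"))
    write_sync(sim$sync, paths$sync)
    utils::write.table(effects, paths$effects, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(expr$expression, paths$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      block = list(chrom = cfg$block_chrom, start_bp = cfg$block_start,
                   end_bp = cfg$block_end),
      chrom_lengths = as.list(cfg$chrom_lengths),
      seed = cfg$seed,
      n_sites = nrow(sim$sites),
      n_xy_sites = sum(sim$sites$class == "XY_fixed_diff"),
      sites = sim$sites,
      genes = expr$truth), paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
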