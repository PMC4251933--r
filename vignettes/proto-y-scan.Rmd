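---
title: "Scanning pooled genomes for a young sex-determining block"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning pooled genomes for a young sex-determining block}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsexscan)
```

## The problem

Young sex chromosomes begin as ordinary autosomes that acquire a
sex-determining locus. Inversions that suppress recombination around that
locus create a clonally inherited block — a proto-Y (in XY systems) or
proto-W (in ZW systems) — which then accumulates deleterious alleles and,
as Y-linked copies degrade, shows incomplete dosage compensation: genes in
the block become expressed more strongly in the homogametic sex.

`poolsexscan` detects and characterises such blocks from *pooled*
whole-genome sequencing of one male and one female pool (Pool-seq). With
pools instead of genotypes, everything is estimated from per-site read
counts: a Y-specific allele carried by every X/Y male and no X/X female
sits at chromosome frequency 0.5 in the male pool and 0 in the female
pool. That allele-frequency *pattern* — intermediate in the heterogametic
sex, fixed or nearly fixed in the other — is the unit of evidence the scan
counts.

## The statistics

**Per-site frequencies.** Each sync record carries A/T/C/G/N/deletion read
counts for both pools. N and deletion reads are excluded throughout. Each
site is reduced to the two alleles with the highest pooled counts (ties
broken alphabetically); the reported frequency is that of the pooled
*minor* allele within each pool, over the two retained alleles. Using one
shared allele axis for both pools prevents a site fixed for *different*
alleles in the two pools from ever counting as the intermediate/fixed
pattern.

**Pooled F~ST~.** The classical π-based estimator. For pool $i$ with
retained-read depth $C_i$ and minor-allele frequency $f_i$,

$$\pi_i = \frac{C_i}{C_i-1}\,2f_i(1-f_i), \qquad
\pi_\text{within} = \tfrac{1}{2}(\pi_m + \pi_f),$$

with $\pi_\text{total}$ computed from the summed counts, and
$F_{ST} = (\pi_\text{total} - \pi_\text{within})/\pi_\text{total}$,
clamped to $[0,1]$ (the finite-depth correction $C/(C-1)$ can push the raw
ratio slightly negative at balanced sites). Sites need at least 2 retained
reads per pool; sites monomorphic across both pools have no defined
F~ST~.

**Fisher's exact test.** Per site, the 2×2 table of pools × alleles is
tested two-sidedly by the *sum of small p* convention: the p-value is the
sum of hypergeometric probabilities of all tables (same margins) whose
probability does not exceed the observed table's. Conventions for
two-sided exact tests differ, so the package fixes this one explicitly; it
is the same convention as `stats::fisher.test`, which the test suite uses
as an independent cross-check of the package's own enumeration.

**Sex-pattern SNPs.** A coverage-eligible site (≥ 10 A/T/C/G reads in
*each* pool, configurable) qualifies when the shared minor allele has
frequency in $[0.3, 0.7]$ in the intermediate pool and $\le 0.1$ or
$\ge 0.9$ in the other pool. All four bounds are applied inclusively.
Polarity is a switch: `"xy"` makes the male pool the intermediate one,
`"zw"` the female pool. Qualifying SNPs are counted in non-overlapping
10-kb windows tiling every chromosome of the sequence dictionary.

**Block calling.** The differentiated block is the maximal run of windows
with at least `count_threshold = 5` qualifying SNPs, bridging up to
`max_gap_windows = 20` consecutive sub-threshold windows, and discarding
runs spanning fewer than `min_run_windows = 50` windows (500 kb). These
defaults are deliberate: at proto-Y-scale densities (thousands of
qualifying SNPs per Mb inside, tens per Mb outside) the inside windows
carry ~20 SNPs each, so a threshold of 5 is permissive inside the block
yet far above the background, the 500-kb minimum suppresses isolated
background clusters, and the 200-kb gap allowance tolerates
coverage-starved stretches. Region membership of a window (or a gene) is
decided by its midpoint, avoiding double counting at boundaries.

**Density arithmetic.** Region summaries report SNP counts and per-Mb
densities, `n / (length_bp / 1e6)`, for the called block and its
complement; the complement's denominator (total genome length) is a
configuration input, since assembled and anchored genome lengths may
differ. Per-window means and SDs (sample SD, $n-1$) are reported both
over all windows and over coverage-eligible windows, since either
accounting is defensible.

**Effect classes.** Variant-effect prediction is out of scope; the
package consumes a prediction table (site → effect class, gene) and maps
SnpEff-style terms onto the closed vocabulary `STOP_GAIN, STOP_LOST,
START_LOST, SPLICE_SITE, NON_SYNONYMOUS, OTHER`. Only sites that are
qualifying sex-pattern SNPs are tallied. Stop gains and losses are also
pooled into a `STOP_CHANGE` row, since either direction disrupts the
coding sequence.

**Expression bias and enrichment.** A gene model with FPKM below 0.05 in
*both* sexes is excluded; otherwise it is assigned to the sex with the
larger FPKM — including the case where one sex has FPKM 0 and the other
expresses, which counts toward the expressing sex. Equal non-excluded
FPKMs are a tie and count in neither class (ties have probability ~0 in
continuous data; the rule only matters for rounded inputs). Enrichment of
female-biased models inside the block is tested with a Yates-corrected
chi-square on {inside, background} × {male, female},

$$\chi^2 = \sum \frac{\max(|O-E| - 0.5,\, 0)^2}{E},$$

with 1 df. The truncation at zero (not universal among software) makes
perfectly proportional tables score exactly 0. The default background is
the *genome-wide* classified set, block included — comparing the block's
composition against the overall composition; `background = "outside"`
compares against the complement instead. With ~230 models inside versus
~21,000 genome-wide the two constructions differ only slightly, but the
default is the one under which the canonical 2×2 composition
(68, 162 vs 7,977, 13,375) yields $\chi^2 = 5.58$.

## The synthetic study design

`simulate_genome()` emulates a family-pooled XY cross, so every stage of
the pipeline runs with no external data:

* two 40-Mb chromosomes, with the differentiated block planted at
  10.1–18.9 Mb (8.8 Mb) on LG1;
* pools of 58 males and 33 females; per-site coverage Poisson with means
  33 (male) and 37 (female), optionally negative-binomial;
* Y-specific fixed differences at rate $2\times10^{-3}$ per bp inside the
  block: every male is an obligate X/Y, so the Y allele sits at
  chromosome frequency exactly 0.5 in the male pool (no inter-individual
  variance — this matches a family cross; an optional `x_polymorphism`
  rate lets the X carry the alt allele in females);
* shared background polymorphism at $2.5\times10^{-5}$ per bp with allele
  frequency Uniform(0.05, 0.95) common to both sexes — such sites can
  qualify by sampling noise, producing a realistic nonzero outside
  density;
* per-read error 0.002; alt read counts Binomial with success probability
  $f(1-\varepsilon) + (1-f)\varepsilon$;
* sparse emission: only variant positions are written (a variants-only
  sync), which keeps an 80-Mb genome to ~20,000 sites. Window
  eligible-position counts therefore refer to emitted sites, not every
  base;
* expression: 22,411 gene models, 234 of them inside the block (the scale
  of a teleost gonad transcriptome), 4.7% excluded by the FPKM filter,
  69% of classified models female-biased inside the block versus 60%
  elsewhere; FPKMs are log-normal with the lower-expressed sex at a
  random fraction of the higher one, and 5% of genes have FPKM exactly 0
  in the lower sex to exercise the zero-vs-expressed rule;
* effect annotations drawn per variant site at rates matching an
  annotated vertebrate genome (non-synonymous ~0.9%, stop/start/splice
  each well below 0.1%).

What the generator does *not* emulate: read-level artefacts (mapping
bias, paralogous alignment, indels), linkage between nearby sites,
coalescent population structure, X-linked diversity gradients, and
reference bias from an X/X reference individual. Passing tests on
synthetic data therefore demonstrate that the *statistics and calling
logic* behave as designed, not that real libraries are free of those
artefacts. Real-data quantities that depend on them — genome-wide mean
F~ST~, exact per-window means — are checked only as qualitative analogues
(the inside/outside density contrast, top-window concentration, block
boundary recovery).

## Numerical and design choices

* Threshold inclusivity: all four classifier bounds inclusive; applied
  uniformly rather than mixing open/closed intervals.
* Coverage filter: "at least 10 reads" is required in *each* pool — the
  stricter reading, since a frequency from < 10 reads is unreliable in
  either pool; configurable via `min_cov`.
* Sites retained for mean-F~ST~-style summaries are all computable sites;
  no SNP-caller pre-filter is applied (the scan operates on every sync
  position).
* Fisher p-values guard probability comparisons with a `1 + 1e-7`
  relative factor so exact ties of symmetric tables are not lost to
  floating-point noise.
* Degenerate inputs: zero-coverage sites are flagged and excluded rather
  than erroring; empty window tracks and empty regions return empty
  results; a degenerate chi-square margin is an error at the
  `yates_chi2()` level and an `NA` report at the `enrichment_report()`
  level.
* Determinism: a `sim_config()` seed fixes all simulation randomness;
  identical configurations reproduce output files byte-identically.

## Problem sizes used in the test suite

The shipped tests run the full default simulation (80 Mb, ~20,000 variant
sites) across 20 seeds for block recovery, 200 seeds of the
expression-only generator for null calibration and another 200 for power,
and an exhaustive Fisher-vs-enumeration sweep over all 2×2 tables with
total count ≤ 40 (~136,000 tables). These sizes make the suite complete
in well under a minute while leaving the stochastic checks enough
replicates to be meaningful.

## Limitations

* The scan assumes exactly two pools; multi-pool designs need external
  reduction.
* Multi-allelic sites are forced biallelic (two highest pooled counts);
  genuinely triallelic signals are invisible.
* The block caller reports rectangular runs of windows; it does not model
  breakpoints or partial-recombination edges.
* Density denominators are as configured — whether "outside" means
  assembled-minus-block or anchored-minus-block is the user's choice.
* Percentage summaries in expression reports are computed from the
  package's own counts with a single denominator (classified models);
  external tables computed with mixed denominators will not match
  exactly.
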