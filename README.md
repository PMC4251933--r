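# poolsexscan

Pool-seq genome scans for young, still-differentiating sex chromosomes.

When a new sex-determining locus arises and recombination around it is
suppressed (typically by an inversion), the sex-limited haplotype — a
proto-Y in XY systems, a proto-W in ZW systems — starts to diverge from
its homolog. Sequencing a pool of males and a pool of females makes that
divergence visible without genotyping anyone: a Y-specific allele carried
by every X/Y male and no X/X female sits at read frequency ~0.5 in the
male pool and ~0 in the female pool. `poolsexscan` finds and
characterises chromosomal blocks enriched for that signature. It is
aimed at researchers mapping nascent sex-determining regions in fish,
amphibians, insects and other groups with young or turnover-prone sex
chromosomes.

## What it computes

From a Popoolation2-style `sync` file (per-position `A:T:C:G:N:del` read
counts for the two pools):

* **Per-site frequencies** — each site reduced to the two alleles with
  the highest pooled counts; frequencies of the shared minor allele per
  pool.
* **Per-site F<sub>ST</sub>** — the classical π-based pooled estimator:
  π<sub>i</sub> = C<sub>i</sub>/(C<sub>i</sub>−1) · 2f<sub>i</sub>(1−f<sub>i</sub>),
  F<sub>ST</sub> = (π<sub>total</sub> − π<sub>within</sub>)/π<sub>total</sub>,
  clamped to [0, 1].
* **Per-site Fisher's exact test** — two-sided ("sum of small p") on the
  2×2 pools × alleles table.
* **Sex-pattern SNPs** — sites with the minor allele at frequency
  [0.3, 0.7] in the heterogametic-sex pool and ≤ 0.1 or ≥ 0.9 in the
  other, at ≥ 10 reads coverage in each pool; counted in non-overlapping
  10-kb windows (XY/ZW polarity is a switch).
* **Block calling and densities** — maximal runs of SNP-dense windows
  become the differentiated block; counts are converted to per-Mb
  densities inside vs outside.
* **Effect-class summaries** — a SnpEff-style annotation table is
  intersected with the sex-pattern SNPs and tallied (stop gains/losses,
  start losses, splice sites, non-synonymous) per region.
* **Expression enrichment** — gene models classified male-/female-biased
  from per-sex FPKM (0.05 exclusion filter), and a Yates-corrected χ²
  tests whether female-biased models are enriched inside the block —
  the signature of incomplete dosage compensation.
* **Synthetic studies** — `simulate_genome()` generates sync, effect,
  expression and truth files for a planted proto-Y design (default: an
  8.8-Mb block on a 40-Mb chromosome, pools of 58 males / 33 females at
  33×/37× coverage), so the whole pipeline is testable offline.

## Worked example

```r
library(poolsexscan)

cfg <- sim_config(seed = 42)          # planted block at LG1:10.1-18.9 Mb
sim <- simulate_genome(cfg)
res <- run_pipeline(sim$sync,
                    effects      = sim$effects,
                    expression   = sim$expression,
                    chrom_lengths = cfg$chrom_lengths,
                    compute_site_stats = FALSE)
res
#> Proto-Y pool-seq scan
#>   19452 sites, 16994 sex-pattern SNPs, 1 region(s) called
#>   block: LG1:10100001-18900000 (8.80 Mb)
#>   SNP density: 1930.795/Mb inside vs 0.042/Mb outside
#>   expression: 70 male- vs 156 female-biased inside, chi2 = 7.89 (p = 0.00497)
```

The scan recovered the planted block to the exact window boundaries
(10,100,001–18,900,000 bp). The density contrast — ~1,931 qualifying
SNPs/Mb inside versus ~0.04/Mb outside — is the hallmark of a
recombination-suppressed proto-Y block; outside SNPs arise only when
shared background polymorphism mimics the pattern by sampling noise. Of
the gene models inside the block, 156 of 226 classified (69%) are
female-biased versus 60% genome-wide, and the Yates χ² of 7.89 (1 df,
p ≈ 0.005) flags that enrichment — consistent with early Y degeneration
without full dosage compensation. `summary(res)` returns all headline
numbers as a list; `plot(res)` draws the per-window SNP track with the
called block shaded; passing `out_dir=` writes the TSV/IGV/BED/JSON
report bundle.

A thin command-line wrapper is installed at
`inst/scripts/poolsexscan-cli.R`
(`Rscript poolsexscan-cli.R simulate|run ...`).

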