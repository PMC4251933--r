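Package: poolsexscan
Title: Pool-Seq Scans for Young Sex Chromosome Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome scans for sex-linked differentiation from pooled
    whole-genome sequencing of a male and a female pool. Reads
    Popoolation2-style sync allele-count files, computes per-site pooled
    F_ST and Fisher's exact tests, classifies sex-pattern SNPs (sites at
    intermediate frequency in the heterogametic-sex pool and fixed or
    nearly fixed in the homogametic-sex pool), counts them in
    coverage-filtered non-overlapping windows, calls differentiated
    blocks and their per-Mb SNP densities, summarises variant effect
    classes inside and outside the block, and tests for enrichment of
    sex-biased gene expression with a Yates-corrected chi-square. A
    synthetic proto-Y data generator provides pool-seq, effect and
    expression tables with known truth so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
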