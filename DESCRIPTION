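Package: divergescan
Title: Comparative Genome Divergence Scanning from BLAST Top Hits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome analyses of nucleotide divergence between
    a draft de novo assembly and one or more reference genomes, built around
    blastn tabular top hits. Implements running-sum (Mott-style) quality
    trimming of sequencing reads with ambiguity and Smith-Waterman adapter
    removal, an E-value step-down ingestion of BLAST tabular output with
    deterministic top-hit tie-breaking, a composite
    percent-identity-per-alignment-length divergence statistic with
    nearest-rank percentile outlier calling, a Lilliefors-corrected
    Kolmogorov-Smirnov normality test with Monte-Carlo p-values, Neighborhood
    Quality Standard (NQS) biallelic SNP filtering over text pileups, a
    quality-control battery (pairwise correlations, contig-size outlier
    overlap, chi-square SNP enrichment), and a seeded synthetic-data generator
    with ground truth so the whole pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    stats,
    tools,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
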