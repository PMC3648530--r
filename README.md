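# divergescan

Whole-genome scanning for extreme nucleotide conservation and divergence
between a fragmented draft *de novo* assembly and well-annotated reference
genomes, using nothing more exotic than blastn tabular top hits — plus the
supporting stages such an analysis needs: quality-aware read trimming,
E-value step-down hit ingestion, Neighborhood Quality Standard (NQS) SNP
filtering, and a quality-control battery. A seeded synthetic-data generator
with ground truth makes every stage testable offline.

## Who this is for

Groups assembling genomes for non-model species (the motivating case is a
large parrot assembly aligned to chicken and zebra finch) rarely have the
annotation depth for classical selection scans (dN/dS over gene models).
`divergescan` implements an annotation-free alternative that uses **every
contig**, coding or not, and asks a single question per contig: how much
identity does its best reference alignment show, per aligned base?

## The statistic

For each contig's top blastn hit, the composite score is

```
score = (pident / 100) / alignment_length
```

Low scores mean high identity maintained over long alignments (extended
conservation); high scores mean the best the aligner could find was a short
near-perfect seed (putative divergence). The observable maximum is
`(100/100)/19 = 0.052631579` — a 19 bp alignment at 100% identity, which is
exactly the shared signature of diverged outlier contigs. The distribution
over a genome's contigs is strongly right-skewed (confirmed here by a
Lilliefors-corrected Kolmogorov–Smirnov test with Monte-Carlo p-values), so
outliers are called non-parametrically: nearest-rank percentile bounds at
0.02% and 99.98% of the ordered distribution, with contigs *equal to or more
extreme* than a bound flagged as conserved or diverged outliers.

Supporting stages:

* **Read trimming** — Mott-style running sum of `limit − P_error(Q)` with
  reset at zero (`limit = 0.05`), terminal-N trimming (cap 3), and
  Smith-Waterman adapter removal (+1/−2/−3).
* **Hit ingestion** — BLAST outfmt-6 parsing; E-value step-down
  (1e-50 → 1e-25 → none) with top-hit ties broken by bitscore, then
  alignment length; per-chromosome identity summaries;
  unique-chromosome classification.
* **QC battery** — pairwise Pearson/Spearman correlations among contig size,
  GC, identity and alignment length; overlap of contig-size percentile
  outliers with divergence outliers; multi-hit summation rescoring of
  conserved outliers; refutation of diverged outliers by longer, more
  significant alternate alignments.
* **SNP filtering** — NQS over samtools-style text pileups (window 11 bp,
  central/average quality ≥ 20, ≤ 2 gaps+mismatches per read window,
  qualified coverage 10–60X, variant frequency ≥ 35%, biallelic only), with
  per-kb density summaries excluding Z/W.

## Worked example

```r
library(divergescan)

p      <- sim_params(seed = 42, n_contigs = 5000)   # the stated world
sim    <- simulate_contigs(p)                       # FASTA + truth table
hits   <- simulate_alignment_table(p, sim$truth)    # blastn-like top hits
top    <- evalue_stepdown(hits, cutoffs = c(1e-50, 1e-25, Inf))
table(top$stage)
#>    1    2    3
#> 3504  771  724

scores <- data.frame(contig_id = top$qseqid,
                     score = composite_score(top$pident, top$length))
rep    <- call_outliers(scores, outlier_params())   # 99.98 / 0.02
rep
#> outlier_report: n = 4999, bounds [3.87055e-05, 0.047619]
#>   conserved outliers: 1
#>   diverged outliers:  1

lilliefors_normality(scores$score, nrep = 2000, seed = 1)$p_value
#> [1] 0.0004997501   # right-skewed, decisively non-normal
```

The two planted outliers (one conserved, one diverged — 0.02% of contigs,
matching the percentile tails) are exactly the contigs recovered; the upper
bound 0.047619 is 1/21, a diverged contig's short-perfect-hit score.

Full pipeline from a JSON config (stages: simulate, trim, ingest, outliers,
qc, snps), writing inspectable intermediates and an md5 manifest:

```r
run_pipeline(list(seed = 11, outdir = "run1",
                  sim = list(n_contigs = 1000)))
```

or from a shell: `inst/scripts/divergescan all --config cfg.json`.

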