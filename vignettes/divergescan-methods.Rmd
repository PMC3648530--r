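---
title: "divergescan: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divergescan: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergescan)
```

This vignette is the package's own account of its science: the models and
procedures implemented, the parameters that matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

## 1. The divergence model

### The composite score

For a contig whose best local alignment to a reference genome reports
percent identity $p$ and alignment length $L$ (bp), the composite score is

$$ s \;=\; \frac{p/100}{L}. $$

The numerator is the identity *fraction*, so $s \in (0, 1]$ and is
dimensionally "identity per aligned base". The two regimes are asymmetric by
construction:

* **Conservation** (small $s$): high identity maintained over a long
  alignment. A 95% identity alignment over 25 kb gives $s \approx 3.8
  \times 10^{-5}$.
* **Divergence** (large $s$): when a contig has genuinely drifted away from
  the reference, a local aligner does not return a long poor alignment — it
  returns the best short seed it can find. The shortest alignment blastn
  reports in practice is about 19 bp, and a perfect 19-mer gives the
  observable maximum $s = 1/19 = 0.052631579$. Diverged outliers therefore
  pile up on a handful of *identical* score values ($1/19, 1/20, 1/21,
  1/22$), which drives the tie rule below.

The statistic is related to the proportional distance between aligned
sequences but deliberately keeps the alignment length in the denominator
untransformed: it is a screening statistic over hundreds of thousands of
contigs, not an evolutionary distance estimate.

### Percentile outlier calling

The score distribution over contigs is strongly right-skewed and resists
standard transformations, so outliers are called non-parametrically.
`call_outliers()` places bounds at the **nearest-rank** percentiles of the
ordered scores — the value at index $\lceil p/100 \cdot n \rceil$ — at
0.02% and 99.98% by default, and flags contigs whose score is *equal to or
more extreme* than a bound. The inclusive rule is not a convenience: the
upper tail is a run of tied values (short perfect hits), and the percentile
cut typically lands inside that run; excluding ties would split
indistinguishable contigs arbitrarily.

Degenerate inputs: fewer than `min_n` scores (default 100) or coinciding
bounds are errors — percentile tails of tiny or constant samples are
meaningless. `min_n` is a parameter because sub-100 samples are legitimate
in unit tests and toy analyses.

For continuous data at the defaults, the closed interval captures fraction
$(\lceil 0.9998\,n\rceil - \lceil 0.0002\,n\rceil + 1)/n$ of the points —
99.961% at $n = 10^5$ — always above the 99.9% working figure.

### Normality testing

`lilliefors_normality()` computes the Kolmogorov–Smirnov distance between
the sample and a normal with mean and variance *estimated from that sample*.
Because the parameters are estimated, the classical KS null is wrong
(anti-conservative); the p-value is taken from a Monte-Carlo null (default
10,000 seeded replicates). The null distribution of the statistic depends
only on $n$, so `lilliefors_null()` lets a calibration loop reuse one null —
the package's type-I-error test runs 1,000 trials against a single
10,000-replicate null rather than $10^7$ simulations. The statistic is
affine invariant, which the tests assert directly.

### Quality controls on outlier status

Three checks probe whether something other than sequence divergence drives
outlier status:

1. **Correlation structure** (`pairwise_correlations()`): Pearson and
   Spearman (average ranks) over contig size, GC, identity, and alignment
   length. The informative pattern is a moderate positive size-vs-alignment-
   length correlation with weak everything-else.
2. **Size overlap** (`size_outlier_overlap()`): the identical percentile
   rule applied to the contig-size distribution; a near-empty intersection
   with the divergence outliers argues against contig size being
   deterministic for the result.
3. **Multi-hit rescoring** (`recompute_conserved_multi()`): for large
   conserved contigs with several non-overlapping syntenic hits, the score
   is recomputed by summation,
   $$ s_{pooled} = \frac{\sum_i (p_i/100)\,L_i}{\left(\sum_i L_i\right)^2}, $$
   i.e. pooled identity fraction divided by total alignment length. The form
   is constrained by two requirements: a single hit must reduce exactly to
   the top-hit score, and appending aligned length at comparable identity
   must move the score toward conservation (it provably does whenever the
   appended hit's identity fraction does not exceed the pooled fraction).
   The eligibility guideline in the source analysis (hits spanning >85% of
   the contig) gates which contigs are *worth* rescoring, not the formula.
4. **Refutation** (`refute_outliers()`): a diverged outlier is dropped only
   on strong evidence — an alternate alignment that is longer, more
   significant (lower E-value), *and* whose recomputed score falls strictly
   inside the interval bounds. All removals are logged with the evidence.

## 2. Read trimming

Quality trimming is the running-sum ("modified Mott") scheme: per base,
$m_i = \text{limit} - P_{error}(Q_i)$ with $P_{error} = 10^{-Q/10}$ and
limit 0.05 (so bases below Q13 count against the read); the running sum
resets to zero when it would go negative; the retained segment ends at the
(leftmost) maximum of the running sum and starts at the first position after
the preceding reset. That segment is exactly the maximum-sum contiguous
substring of the $m_i$, which is what the test suite asserts against an
exhaustive $O(n^2)$ oracle. A read whose running sum never rises above zero
is discarded.

Open interpretation settled here: "the first positive value of the running
sum" is read *locally* — the start of the segment containing the argmax. A
global reading (first positive position in the whole read) would prepend
negative-sum stretches to the kept read, defeating the purpose of trimming.
Ties at the maximum keep the leftmost (shortest read), deterministically.

Ambiguity trimming removes terminal N runs entirely. The cap of 3 governs
*tolerance*, not removal: a longer terminal run, or more than 3 internal Ns,
flags the read in the stage log. Internal Ns are never excised — excising
them would silently shift coordinates of everything downstream.

Adapter removal is local Smith-Waterman (match +1, mismatch −2, gap −3,
linear) of each adapter against the read; any match scoring at least
`sw_min_score` is removed **together with all bases 3′ of it** (standard
adapter read-through semantics: sequence after the adapter is synthesis
artifact, not insert), repeating until no match remains. The implementation
uses Biostrings' alignment engine; the tests check it against an independent
dynamic-programming oracle.

Stage order is quality → ambiguity → adapter, composed into a single kept
interval on the original read coordinates. The pipeline is idempotent on the
generator's reads; note that idempotence is not a mathematical certainty for
arbitrary inputs (re-quality-trimming a read whose 3′ end was removed by the
adapter stage can in principle shrink it further), which is why it is tested
on the stated world rather than asserted as a theorem.

## 3. Alignment ingestion

The E-value step-down (1e-50, then 1e-25, then no cutoff) is a disk-space
workflow, not a statistical one: each stage exports and resolves the queries
whose best hit passes the stage cutoff, and only unresolved queries continue.
Its defining property — proven as a property test — is that the final
retained hit per query is identical to a single-pass unrestricted top-hit
selection, because a query's globally best hit is the one that passes the
earliest stage the query can pass.

Top-hit selection is a deterministic total order: minimum E-value, ties by
maximum bitscore, then maximum alignment length (ties in practice occur
almost exclusively at E-value 0), then lexicographically smallest
`(sseqid, sstart)` as a final, arbitrary-but-fixed key so that row
permutation can never change the result.

Unique-chromosome classification uses **all** retained hits of a contig, not
only the top hit — the stricter reading of "a unique alignment to a single
chromosome". Minus-strand hits (sstart > send) are kept as-is; strand never
enters any statistic. GC is computed over non-N bases to avoid penalizing
gap-padded contigs.

## 4. NQS SNP filtering

A read's observation at a candidate column qualifies when (i) the central
base quality is ≥ 20, (ii) the mean quality over the read's bases in the
centered 11-bp window is ≥ 20, and (iii) the read has ≤ 2 mismatches+gaps in
that window, *excluding the candidate position itself* (otherwise every
alternate-allele read would start one mismatch in the hole). Windows are
clipped at read ends and the average taken over the available positions —
the alternative (discarding the terminal 5 bp of every read) throws away
qualified evidence the filter is designed to keep.

A column is called when the **qualified** depth is within 10–60X, exactly
two alleles (reference plus one alternate) appear among qualified reads, and
the alternate fraction among qualified reads is ≥ 35%. Coverage gates apply
to qualified reads, following the NQS literature; the gap+mismatch cap is
per read-window, likewise. Columns with masked reference (N or lowercase)
are skipped, mirroring SNP prediction against repeat-masked references.

A consequence worth knowing: tightening a *per-read* gate can, in
principle, **increase** the call count at columns sitting above the upper
coverage gate, by dropping qualified depth back into range. Monotonicity of
calls in each threshold therefore holds only while the upper gate is not
binding, and that is how the property is tested.

Pileup threading: the text pileup parser tracks read identity across columns
using the `^`/`$` markers under the convention that continuing reads precede
newly started reads within a column — true for coordinate-sorted input as
produced by samtools and by the package's generator. Indel annotations are
skipped (indel calling is out of scope); `*` is retained as a gap
observation that disqualifies and counts against the window cap.

## 5. The synthetic-data generator

The generator produces a *stated world*: a fragmented avian-like draft
assembly aligned to a distant reference, with planted ground truth.

| Parameter | Default | Why |
|---|---|---|
| `n_contigs` | 5,000 | desk-scale stand-in for a 283k-contig assembly |
| contig lengths | lognormal, meanlog 8.0, sdlog 0.45, clipped 500–30,000 bp | median ≈ 3 kb, matching the N50 scale of a short-read avian draft; 500 bp is the assembler's minimum contig size |
| `gc_mean` | 0.42 | avian genome-wide GC |
| background identity | Normal(74, 6), clipped 60–92% | 74% is the genome-wide median identity of the motivating macaw-chicken alignment |
| background alignment length | Uniform(0.05, 0.45) × contig size, floor 150 bp | yields Pearson r(size, alignment length) ≈ 0.65, inside the empirical 0.55–0.75 band |
| chromosome offsets | GGA16 +6, GGAZ −3 | plants the reported ordering (GGA16 highest, GGAZ lowest); the magnitudes are generator inventions large enough to be recoverable at desk scale |
| planted conserved | 0.02% of contigs; length 0.9–1.0 × max; identity 95–99 over ≥ 90% of the contig | scores ≈ 3.3–4.1 × 10⁻⁵, provably below any background score |
| planted diverged | 0.02% of contigs; 500–1,782 bp; one 19–22 bp embedded motif, hit at 100% | the short-perfect-alignment signature; scores 1/22–1/19, provably above any background score |
| bitscore model | `len × (5.6 p − 3.6)`, floor `0.2 len` | anchors a 74%/759 bp alignment near E ≈ 1e-112 and a perfect 19-mer near E ≈ 4, so step-down stages are all exercised |
| read qualities | mean Q35, slope −0.1/cycle, sd 3, clipped 2–40 | Illumina-like decay |
| pileup base qualities | Normal(35, 3), clipped 10–40 | modern Illumina scale; error rate ≈ 3 × 10⁻⁴ |
| `variant_fraction` | 0.002 | 1 SNP / 0.5 kb at pileup scale; planted positions spaced ≥ 11 bp |

Planted outlier counts default to 0.02% of contigs deliberately: the
percentile caller flags ~0.02% of contigs per tail by construction, so a
planted fraction above that makes high sensitivity arithmetically
impossible, and one far below it tests nothing.

Planted variant columns are made *exactly* biallelic with alternate
fraction ≥ 0.5 by placing the alternate allele on every other covering read
— a balanced heterozygote. Sequencing errors at the quality-implied rate are
injected everywhere else. Per-contig coverages are drawn mostly inside the
10–60X gates with deliberate low- and high-coverage contigs, so the truth
table records some planted variants as unrecoverable (depth outside range).

What the generator does **not** emulate — and hence what a green test does
not establish: instrument-specific error and quality profiles; indels and
structural variation; repeat families and low-complexity sequence (so the
specificity figures say nothing about repeat-driven false calls on real
data); scaffolding gaps; library-specific adapter chemistry beyond a
planted read-through; true evolutionary divergence processes (the diverged
class is "novel sequence plus one conserved motif", which reproduces the
*signature* of divergence outliers, not their etiology). Alignment tables
are generated parametrically rather than by running an aligner: running
blastn is explicitly out of scope, and the pipeline consumes its tabular
output only.

## 6. Numerical and convention choices

* **Phred conversion**: $P_{error} = 10^{-Q/10}$, the standard relation.
* **Percentiles**: nearest-rank on the ordered sample; no interpolation.
  Interpolating conventions (R's `quantile` types 4–9) produce values that
  are not order statistics, which would break the inclusive tie rule.
* **Seeding**: one master integer seed; every generator derives a fixed
  sub-stream (`derive_seed`), and all seeded code saves and restores the
  caller's RNG state. Identical parameters reproduce byte-identical files.
* **Tie-breaks**: top-hit selection ends in `(sseqid, sstart)`; the
  quality trimmer keeps the leftmost maximum; both are arbitrary but fixed.
* **Chi-square**: the enrichment test treats each bp as a Bernoulli trial
  (SNP vs not), giving a 2×2 table with 1 df, Pearson statistic, no Yates
  correction — the counts involved are in the 10⁴–10⁶ range where the
  correction only biases. Expected cells < 1 attach a validity warning
  rather than an error.
* **Empty/edge inputs**: empty FASTQ and empty hit tables round-trip as
  empty outputs; empty reads are results, not errors; a query with no hits
  is an absence signal, not an error.

## 7. Known limitations

* The composite score depends on the top hit only (by design); the
  multi-hit rescoring is a QC cross-check, not a replacement statistic.
* The refutation step consumes an alternate-hit table supplied by the user;
  the package does not itself search external sequence databases.
* The pileup parser assumes the samtools column-ordering convention for
  coordinate-sorted input; pileups of unsorted BAMs may thread incorrectly.
* Paired-read trimming synchronization, quality recalibration, indel
  calling, and genotype likelihoods are out of scope.
* The Lilliefors p-value floor is $1/(B+1)$ for $B$ Monte-Carlo replicates;
  with the default $B = 10^4$, "p < 0.001" is the strongest statement a
  single test can make at the default settings.
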