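---
title: "Methods: binned DMR calling, TE expression and small-RNA classification on synthetic germline data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned DMR calling, TE expression and small-RNA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigerm)
```

This vignette documents the models, parameter choices and numerical
conventions behind `epigerm`, and what its synthetic-data tests do and do
not establish about real sequencing data.

## Coordinate and counting conventions

All genomic coordinates in memory are 0-based half-open; 1-based on-disk
formats (cytosine reports, RepeatMasker-style tables, SAM) are converted
once at the I/O boundary and nowhere else. Methylation is always
`#C / (#C + #T)`: the fraction of bisulfite reads reporting C among reads
reporting C or T at a reference cytosine. Strand-specific cytosines are kept
as separate records — symmetric CpG merging would change per-site coverage
and therefore the ≥ 4-read qualifying filter. Genome-wide levels are
count-weighted (pooled counts), not means of per-site levels; a per-site
mean is exposed as an option because either reading of a "total methylation
level" is defensible.

## The DMR model

The caller works on fixed-width bins (500 bp default), never on merged or
smoothed segments, so a "DMR" is exactly one bin. Per bin the pooled CpG
counts of the two genotypes form a 2×2 table
`[[mC_case, uC_case], [mC_control, uC_control]]` tested with a two-sided
Fisher exact test, implemented directly as the sum of hypergeometric
probabilities of all tables no more probable than the observed one. Tables
whose probability is within a relative tolerance of 1e-7 of the observed
probability count as ties and are included; this makes the two-sided sum
reproducible across floating-point implementations, and the suite verifies
exact agreement (relative error < 1e-10) with lchoose-based enumeration
over every 2×2 table with total ≤ 60. Degenerate tables (any zero margin)
get p = 1 by convention.

Benjamini–Hochberg runs across the *testing universe*: bins with at least
one covered CpG in both genotypes. Untestable bins carry no p-value, so
they do not belong in `m`. Selection requires `|delta| >= 0.50` (absolute
difference of pooled levels) and `q < 0.05`; the retention filter
(≥ 4 CpGs each ≥ 4 reads, in both genotypes) is applied *after* selection,
following the procedure's stated order. Because the order is genuinely
ambiguous in such procedures, `prefilter_universe = TRUE` applies the
retention filter before testing instead, shrinking the BH universe; raw
p-values are unchanged, adjusted values grow with the larger default
universe. Swapping the genotypes flips every direction label and preserves
p and q exactly — a property the suite asserts.

With the default thresholds the 50-percentage-point delta filter dominates
the FDR filter: in null simulations (no planted effect, 10,000 bins, 20×
coverage) the caller returns essentially zero bins, which the acceptance
suite checks across five seeds.

## Matched control regions

Controls are one-per-DMR random draws constrained to (1) the DMR's
chromosome, (2) *exactly* the same number of qualifying CpGs in the
control genotype, and (3) a control-genotype methylation level within 0.05.
"Same coverage of CpGs" is operationalised as the equal count of
qualifying sites because that is the only exact, testable reading; equal
summed read coverage is a plausible alternative we deliberately did not
implement as the default. Candidates are filtered exactly rather than
rejection-sampled, each bin is used at most once, and sampling is uniform
under a named seed substream. A DMR with no qualifying candidate is
reported unmatched; the run fails only when more than 10% are unmatched.
In the bundled pipeline controls are drawn for the hypomethylated DMR set,
the set whose feature-overlap enrichment they serve as the null for.
Hypermethylated planted bins in the simulator lower the *control*
genotype's methylation, so their control-genotype levels are atypical by
construction and no level-matched control can exist for them — another
reason the control machinery follows the hypo set.

## TE-family expression

Each read's unit mass is split evenly over its reported genomic alignments
(`weight = 1/n_hits`); reads with more than 10,000 sites are discarded
entirely. A hit belongs to a repeat body iff its 5′-most aligned base lies
inside the repeat interval — an unambiguous rule for 50-bp reads spanning
boundaries; a hit whose 5′ base falls into nested repeats is assigned to
the smallest one only, so no single hit is ever counted twice. Family
expression is `score_sum / (mapped_millions × mean_length_kb)` with the
mean over annotated genomic copies (consensus length available as an
option, since "average length of repeats within the family" admits both
readings). Fold changes use a pseudo-expression of 1e-3 so silent families
stay defined; the value is recorded on the result.

rRNA filtering removes reads aligning to any rRNA reference with ≤ 3
mismatches (ungapped, either strand) before weighting. The scan is
accelerated by an exact k-mer seed prefilter with
`k = floor(L / (mismatches + 1))`, which by pigeonhole cannot lose a true
sub-threshold match.

## Consensus ("microgenome") methylation profiles

Bisulfite calls from reads aligned uniquely to repeat consensus sequences
are summarised as per-CG `#C/(#C+#T)` along each consensus. The first 50
bases are flagged `plot_excluded` but retained in the data, since element
starts are typically low-coverage. For LTR elements, whose read orientation
is ambiguous, the profile is averaged with its own reverse complement:
calls are collapsed to CpG-dyad coordinates (the plus-strand C of each CG)
and each dyad pooled with its mirror at `L − 2 − pos`.

## Small-RNA classification

Reads > 24 nt are piRNA candidates; 19–24 nt is the putative-miRNA size
class (the lower bound is the gel-excision window; an annotation-based
miRNA definition would be the natural alternative, but the size class is
the default because it needs no extra annotation). Multi-mapping reads are
annotated by majority vote over at most `k = 10` alignments sampled
without replacement under a seed; each alignment takes the category of the
feature overlapping its 5′ base, ties break by a fixed hierarchy
(`exon > intron > transposon > other_repeat > intergenic`, configurable —
the order follows the conventional listing of annotation classes).
Orientation (sense iff read strand equals feature strand) is the majority
over the alignments carrying the winning category. With ≤ k alignments the
procedure provably equals the exhaustive vote, which the suite asserts
against an independent oracle. Primary piRNAs carry 5′ U; otherwise
position-10 A defines secondary; a read carrying both signatures is called
primary (1U precedence, the convention in ping-pong analyses; a 10A-first
mode exists).

## Chromatin profiles

ATAC reads are corrected to Tn5 insertion points: +4 bp from the leftmost
base on the plus strand, −5 bp from the rightmost base on the minus strand
(the transposase dimer inserts adaptors 9 bp apart). The corrected object
carries a marker so a second shift is an error rather than a silent double
offset. Deduplication keys on (chromosome, 5′ position, strand) and is
idempotent. Coverage matrices count cut sites (or 5′ ends) in fixed
offset bins around a region anchor, scaled to reads per million by the
library size; minus-strand anchors flip offsets so downstream is always
positive. DMR metaplots anchor at the bin midpoint with a ±2-kb flank in
50-bp bins — the window parameters are exposed because no canonical values
exist for them. ChIP signal is library-size normalised only; no input
subtraction is performed.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions used throughout the tests:

* **Genome** (`sim_genome`): uniform random background; per-family
  consensus sequences copied into non-overlapping positions with 2% point
  mutations (enough divergence to exercise both unique mapping and
  ≤ 2-mismatch consensus mapping) until a target repeat density is
  reached; gene models are placed in repeat-free gaps.
* **Methylome** (`sim_methylome`): per-cytosine coverage is
  Poisson(20); methylated counts are Binomial(coverage, p) — the simplest
  generative model matching the pooled-count Fisher test's assumptions.
  Baseline CpG methylation is 0.85 (a late-gestation male germline after
  *de novo* methylation); planted hypo bins set the case probability to
  `0.85 − 0.70`; planted hyper bins lower the control by the same amount.
  Zero-coverage sites are omitted, as a mapper would omit them.
* **RNA** (`sim_rna`): per-family read counts are Poisson with mean
  `expression × kb × library/1e6`, so the family-expression statistic
  recovers the planted level in absolute units; multi-mapping reads place
  at the homologous offset in every family copy (`n_hits` = copy number);
  background transcription fills the library in repeat-free space.
* **Small RNA** (`sim_smallrna`): the default `pirna_params()` fractions
  (long fraction 0.355, 1U 0.75, 10A 0.677, sense 0.573) are derived so the
  expected summary ratios are piRNA/miRNA 0.55, primary/secondary 4.43 and
  sense/antisense 1.34 — a typical embryonic germline small-RNA population.
* **ATAC/ChIP** (`sim_atac`, `sim_chip`): ATAC fragments have two cut
  sites inside open regions (reads emitted so the +4/−5 correction
  recovers them exactly); ChIP reads follow a fold-enrichment density
  model with background strictly outside the enriched regions, plus exact
  duplicates at a set rate.

All draws run in named substreams of one root seed
(`substream_seed(seed, name)`), so stages are individually reproducible
and adding a stage does not perturb the others.

What passing these tests shows: the statistics are implemented exactly
(oracle equivalence), the pipeline recovers planted signal at realistic
coverage, and everything is deterministic. What they do not show: behaviour
under PCR bias, sequencing error, bisulfite non-conversion heterogeneity,
mappability structure, or biological dispersion beyond binomial — the
generator deliberately omits these (a beta-binomial or error-model layer
would be the natural extension).

## Problem sizes and defaults

The bundled study (`sim_study_params()`) uses a 2 × 250-kb genome
(1,000 bins), 20× methylome coverage with 10 planted hypo and 2 hyper
bins, 8,000-read RNA libraries with two families upregulated 5×,
20,000 small RNAs, 5,000 ATAC fragments and 10,000 ChIP reads — sizes at
which every stage's signal is unambiguous while a full `simulate` + `run`
completes in well under a minute. The acceptance checks scale the DMR
stage up to 10,000 bins (5 Mb) with 100 planted bins, the stated
conditions for sensitivity/false-call measurement, and use 50,000 RNA
reads for the weight-conservation and ratio-recovery checks.

## Known limitations

* One bin = one DMR; adjacent significant bins are not merged, so DMR
  counts are bin counts.
* Fisher on pooled counts ignores replicate-level dispersion; genotypes
  are pooled by count addition before testing.
* The rRNA filter is ungapped; indel-containing rRNA fragments would
  escape it.
* `n_hits` is trusted from the aligner's report rather than recomputed.
* Locus-level TE attribution (EM reassignment) and model-based
  differential expression are out of scope; family-level fractional
  counting is the implemented statistic.
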