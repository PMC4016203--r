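---
title: "Counting exon expression from per-base coverage: models and methods"
author: "maxcounts package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting exon expression from per-base coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxcounts)
```

## The measure

Conventional RNA-seq quantification summarizes a feature (here, an exon
or a single-isoform transcript) by its *totcounts*: the number of
alignment records with at least one aligned base inside the feature.
Totcounts grow with feature length — a longer exon offers more sites
for reads to land on — and they inherit every irregularity of the read
coverage along the sequence: priming preferences, secondary-structure
effects, and the under-representation of 3' ends produced by
random-hexamer reverse transcription.

The alternative implemented here is *maxcounts*. Let $N_{ijp}$ be the
number of reads covering base $p$ of exon $i$ in library $j$ (the
coverage profile, `coverage_profile()`). Then

$$\mathrm{maxcounts}_{ij} = \max_p N_{ijp}.$$

The maximum of the per-base counts measures expression at the
best-represented position of the exon. Because the peak depth of a
uniformly sampled exon does not scale with its length (only a slowly
growing extreme-value correction does), maxcounts are far less
length-dependent than totcounts, and because they ignore valleys in the
coverage they are robust to 3' drop-off and to local under-sampling.

Coverage is accumulated from the aligned blocks of each record (CIGAR
`M`/`=`/`X` operations); `N` and `D` gaps contribute nothing, so a
junction-spanning read covers only its aligned segments. Profiles are
built with block-interval difference arrays, $O(\text{blocks})$ per
record, and the test suite checks them against a naive per-base oracle.
Paired mates are counted as two independent records, reads overlapping
several exons are counted for each, and duplicates are not removed —
the summarization deliberately avoids any transcript-model assumption.

## Pre-processing and alignment filtering

`trim_read()` removes the maximal run of bases with Phred quality below
20 from each end of a read (interior low-quality bases stay; trimming
is idempotent), and `filter_length()` discards reads shorter than 33 bp
after trimming — a read of exactly 33 bp is kept. `remate()` restores
mate correspondence after filtering: pairs in which both mates survive
stay pairs, a lone survivor becomes a singleton, and
$2\,\text{pairs} + \text{singletons} + \text{discarded}$ always equals
the input read count. Adapter removal and mapping are outside the
package; it consumes SAM/BAM produced by any spliced aligner.

`filter_alignments()` reproduces the post-processing applied before
counting: all records of multireads (reads reported at more than one
location, detected from the `NH` tag, from secondary/supplementary
flags, or from read-id multiplicity as a fallback) are dropped, as is
every record whose similarity to the reference,
$(\text{aligned bases} - \mathrm{NM})/\text{aligned bases}$, is
*strictly* below 0.97. Soft-clipped bases are excluded from the
denominator because they were never compared to the reference. A
record at exactly 0.97 is kept. Both removals are tallied and logged.

## Normalization

* **TMM** (`tmm_factors()`): the reference library is the one whose
  upper quartile of scaled counts is closest to the mean upper
  quartile; for each library, log-ratios
  $M = \log_2\frac{y_k/N_k}{y_r/N_r}$ and intensities
  $A = \tfrac12\log_2\frac{y_k}{N_k}\frac{y_r}{N_r}$ over exons nonzero
  in both libraries are doubly trimmed (30% on each tail of $M$, 5% on
  each tail of $A$) and averaged with inverse binomial asymptotic
  variances as weights; factors are centred to geometric mean 1.
  Because $M$ and $A$ are library-size scaled, TMM is itself
  scale-free: re-estimating factors on an `apply_size_factors()`-scaled
  matrix therefore requires supplying (equal) library sizes, upon which
  the round trip returns factors near 1.
* **RPKM** (`rpkm()`):
  $\mathrm{RPKM}_{ij} = N_{ij} / (L_i/10^3 \cdot N_{\cdot j}/10^6)$,
  computed from raw counts.
* **Between-lane full-quantile** (`fq_between_lane()`): each library's
  sorted values are replaced by the across-library mean of order
  statistics, mapped back through the library's own ranks. Ties
  receive the mean of the normalized values their ranks span — a
  deterministic, symmetric rule; with ties the sorted columns coincide
  only up to the tied groups.
* **Within-lane full-quantile** (`fq_within_lane()`): exons are
  stratified into 10 equal-size groups by covariate rank (exon length
  is the intended covariate) and, within each library, every stratum is
  mapped onto the mean empirical quantile profile across strata. The
  quantile grid is $(r-1)/(n_s-1)$ with mid-ranks for ties, which
  places each order statistic exactly on R's type-7 quantile grid, so
  strata with identical compositions map onto themselves. Ten strata
  keep roughly 200 exons per stratum on a 2,000-exon experiment —
  enough resolution to flatten the length trend while keeping each
  stratum's empirical quantile function stable.

The low-expression filter drops exons whose *mean raw count across
replicates* is strictly below 0.5 (a mean of exactly 0.5 is kept); it
is applied before normalization and before any diagnostic. When a
grouping is supplied the row must reach the threshold in every group,
so per-group analyses see a common exon set.

## Diagnostics

All curve diagnostics log-transform counts as $\log_2(x+1)$ — the base
is conventional and the $+1$ keeps low but retained exons
representable — and fit a natural interpolating cubic spline through
bin means. Bins are consecutive groups of `bin_size` exons (default
5,000; the last bin may be smaller) after sorting by the covariate;
binning already smooths, so no additional smoothing parameter is
introduced. Each curve also reports the Spearman correlation of the
unbinned pairs as a scalar bias score (defined as 0 when either margin
is constant).

* `distribution_summary()` excludes zero-count exons, sorts counts
  descending, and reports the smallest percentage of exons whose
  counts reach 50% and 90% of the library total.
* `variance_cv_curves()` computes, across the replicates of one group,
  the unbiased variance of log-counts against the mean log-count and
  the raw-scale coefficient of variation (sd/mean) against the log
  mean; both x-axes are affinely rescaled to $[0,1]$ so curves from
  different measures are comparable.
* `spikein_accuracy()` regresses log estimates on log known
  concentrations: Pearson $r$ with the standard t-transform two-sided
  p-value, slope, intercept, residuals. No multiplicity correction is
  applied.
* `delta_stat()` is $(x_A - x_B)/(x_A + x_B)\cdot 100$, the percent
  discrepancy between two transcripts of (near-)equal concentration.
* `relative_variation()` is
  $(X_\mathrm{orig} - X_\mathrm{filt})/(X_\mathrm{orig}+1)\cdot 100$,
  computed on raw counts; the $+1$ avoids division by zero. The
  fraction of exactly-0% entries summarizes robustness to filtering.

## The synthetic-data generator

`simulate_truth()` draws, per exon: a length (log-normal, default
median 300 bp, $\sigma_{\log} = 0.9$, clamped to 50–5,000 bp — an
exon-like distribution), a GC content (Beta(9, 11), centred near
0.45), and an expression level (log-normal, default
$\sigma_{\log} = 1.8$, i.e. about four orders of magnitude between the
2.5th and 97.5th percentiles — the dynamic range of a real
transcriptome). Exons are laid out on one pseudo-chromosome with 100 bp
spacers, so emitted SAM/BED/FASTA files are self-consistent without any
external reference.

**Positional preference.** Real single-isoform transcripts show
reproducible coverage humps and valleys at scales coarser than a read,
and a drop toward the 3' end. The generator therefore draws a
Gamma$(k, 1/k)$ priming efficiency once per *block* (default twice the
read length) and holds it constant within the block; $k \to \infty$
gives uniform coverage, $k \le 1$ highly skewed coverage. An
exponential multiplier with e-folding distance `three_prime_decay`
(default 500 bp, acting over the final $3\times$ that window) models
the 3' drop. Two facets of the preference matter and are kept
separate:

* the *placement distribution* (weights normalized to sum 1) governs
  where reads start, and is shared across all replicate libraries of
  an experiment — the reproducible-pattern property;
* the *overall priming efficiency*, mean/max of the raw per-position
  efficiencies, scales the exon's expected read yield. A transcript
  sequenced efficiently only in a few regions yields fewer reads in
  total, yet its peak coverage still reflects its concentration. This
  is precisely the mechanism that lets totcounts diverge between two
  equal-concentration transcripts with different coverage shapes while
  maxcounts agree; with independent per-position draws instead, the
  preference would average out inside every read-length window and
  neither effect would exist.

Reads per exon are Poisson with expectation proportional to
expression × valid start positions × efficiency, scaled to the
configured library depth; starts are drawn from the placement weights.
Mismatches are injected per base (NM tags kept consistent), a
configured fraction of reads receives enough mismatches to fall below
97% similarity, and a configured fraction is emitted with a second,
secondary-flagged mapping record (NH = 2). `make_spikein_panel()`
builds single-isoform transcripts with log-uniformly spaced known
concentrations on their own reference sequences; their lengths default
to 250–2,000 bp, the span of real spike-in standard panels, rather
than the exon-length distribution.

The generator emulates statistical structure, not sequence realism: no
sequence-dependent error model, no fragment-size distribution, no
flow-cell artifacts, and single-end reads by default (counting treats
mates independently, so single-end exercises all logic). Passing tests
on these simulations demonstrates the algebra and the qualitative
phenomena — length bias, coverage-shape bias, filtering robustness —
not performance on any particular real library.

## Study conditions used by the tests and the acceptance script

The experiment sizes are chosen so each check runs in seconds to a
couple of minutes on one core while staying in the statistical regime
where the phenomena are visible:

* *Length bias*: 2,000 exons, uniform within-exon placement, one
  expected read per valid start position per unit expression
  (≈ 3.5 M reads/library), two replicates; counts are 0.5-mean
  filtered and averaged across replicates before correlating with
  length. With expression varying across exons — as in any real
  library — totcounts correlate strongly with length while maxcounts
  do not. Note that if expression were held constant across exons the
  maximum would still grow like an extreme-value statistic
  (≈ $\sqrt{2\ln m}$ over $m$ independent windows), so a residual
  positive rank correlation of the maximum with length is a property
  of the statistic, not an artifact.
* *Equal-concentration discrepancy*: two 1,000 bp spike-ins at equal
  concentration, one uniform and one with $k = 0.5$ preference,
  10^5 reads, six replicates; raw replicate-averaged counts are
  compared (TMM over a two-feature matrix would be meaningless).
* *Spike-in recovery*: 30 spike-ins over three decades, non-uniform
  coverage ($k = 1$, 500 bp 3' decay), 10^5 reads, six replicates —
  the replicate-group size of the deepest-replicated group in real
  spike-in experiments.
* *Filtering robustness*: 500 exons, 5,000 expected reads (median
  coverage of a few reads per exon), 10% multireads, 5%
  low-similarity reads; counted once from the original and once from
  the filtered alignment set.

## Numerical choices and degenerate inputs

Zero counts participate in full-quantile normalization (they are only
removed by the 0.5-mean filter). An all-zero coverage profile has
maxcounts 0, and maxcounts = 0 exactly when totcounts = 0. A
single-bin bias curve degenerates to a constant function. Spearman
scores of constant vectors are defined as 0. `delta_stat(0, 0)` and
all-zero distribution summaries are errors rather than silent NaNs.
Random draws are fully determined by the configuration seed plus a
per-replicate seed; identical configurations produce byte-identical
FASTQ/SAM/TSV outputs.

## Limitations

Exon-level summarization is deliberate: combining exon maxcounts into
gene- or transcript-level estimates requires a transcription model and
is out of scope, as is differential-expression analysis. The
similarity filter needs `NM` tags (files without them fail loudly
rather than silently skipping the filter). Strand is carried through
the annotation but counting is unstranded. The within-lane
normalization supports one covariate at a time; correcting length via
full-quantile in practice also flattens most of the GC trend.
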