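---
title: "Models and methods behind hicdesk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicdesk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdesk)
```

This vignette explains the statistical models and procedural choices in
`hicdesk`: what each analysis assumes, which parameters matter, and where
the design was genuinely open and a decision had to be made.

## The fragment coordinate system

Everything downstream is keyed to a single fragment table: either the
restriction fragments of a digest or fixed-size bins. Coordinates are
1-based inclusive throughout the package (the IRanges/GRanges convention),
so interval arithmetic can be delegated to the Bioconductor containers;
BED input (0-based half-open) is converted at the reader, and all output
tables are written 1-based inclusive. Fragment IDs are consecutive
integers 1..N in (chromosome order, start) order.

Digestion scans the forward strand for exact, case-insensitive occurrences
of the recognition site and cuts at the enzyme's biochemical cut offset
(HindIII A^AGCTT cuts after one base; DpnII ^GATC before the site). Two
choices deserve note:

* **Cut offset, not motif start.** Cutting at the offset is the physically
  correct fragment boundary; it is configurable per enzyme, and toy
  examples in the tests fix the offset explicitly.
* **Forward strand only, no ambiguity codes.** Hi-C enzymes have
  palindromic sites, making a reverse-strand scan redundant;
  non-palindromic enzymes are accepted but documented as
  forward-strand-only. `N` runs never match, so unsequenced regions never
  gain fabricated cut sites — a conservative choice.

## Read-end processing

Hi-C read-ends are aligned independently, so pairing is by read name: only
ends flagged unique in both files (MAPQ above a configurable threshold,
default MAPQ > 0, and not secondary/supplementary) form pairs; mate tags
(`/1`, `/2`, whitespace suffixes) are stripped first. The
ligation-informative coordinate of an end is its 5' base — leftmost mapped
base on the plus strand, rightmost on minus — and that position is used
both for the proximity filter and for fragment assignment. Pairs are
order-normalized (lower chromosome/position first, ties broken by strand)
so results never depend on which file was called "forward".

The proximity filter addresses two library artefacts: *inward* pairs
(opposite strands pointing toward each other) spanning less than a
threshold are characteristic of uncut DNA, *outward* pairs (pointing away)
of self-ligated fragments. Defaults are 1,000 bp inward and 25,000 bp
outward, both configurable and both optional; inter-chromosomal and
same-strand pairs always pass. These thresholds are conventional values
for 6-cutter libraries, not estimates from data — the generator's artefact
injector uses the same conventions, which is what makes the filter test
exact.

## Tracks

Four track kinds encode different measurement semantics:

| kind | value | aggregation | analysis transform |
|---|---|---|---|
| annotation_count | 1 per spanning feature, 0.5 per partial overlap | sum | log2(x+1) |
| short_count | reads per fragment (5' base) | sum | log2(x+1) |
| density | % bases covered by ≥1 element (union, not depth) | length-weighted mean | none |
| methylation_density | % methylated C (pooled Σm/Σt) | length-weighted mean | none |

Open points we settled: methylation calls are **pooled** per fragment
(Σ methylated / Σ total) rather than averaging per-site ratios, so deeply
covered cytosines carry proportionally more weight; density aggregation is
**length-weighted** (for equal-size bins this is the plain mean, so the
distinction only matters for restriction fragments); fragments without any
covered cytosine are **missing, not 0** — absence of evidence is not 0 %
methylation; strand is read but ignored everywhere; counts are
log-transformed only at analysis time, never at storage time, with a +1
pseudo-count.

## Normalization

**Observed/expected with coverage normalization.** Intra-chromosomal
entries are divided by the mean contact frequency in their distance class;
classes are fragment offsets |i−j|, and the expectation is pooled across
chromosomes by default (`per_chromosome = FALSE` gives the per-chromosome
variant). Pooling makes the *pooled* mean of every diagonal exactly 1;
per-chromosome diagonal means then deviate by their relative coverage,
which is intended — it preserves between-chromosome differences in decay.
Inter-chromosomal entries are divided by (row mean × column mean / overall
mean) of the trans sub-matrix. All-zero distance classes become missing
and are flagged rather than silently zero.

**Iterative correction (ICE).** The observed matrix is modelled as
*O = B W B* with diagonal bias matrix *B*; biases are found by iterative
proportional scaling until the relative spread of unmasked row sums falls
below `tolerance` (default 1e−5, maximum 200 iterations, error on
non-convergence). Bins below the 2nd coverage percentile (configurable)
are masked first — balancing near-empty rows amplifies noise. The bias
vector is normalized to mean 1, which fixes the otherwise arbitrary scale
of *W*. The update is the parallel row-sum rescaling; the test suite
checks it against an independent sequential (Gauss–Seidel, square-root
damped) balancer to 1e−8 on small matrices, and against planted biases on
balanced truth matrices (recovery correlation > 0.99 at 200 bins).

**Poisson regression (HiCNorm-style).** Per chromosome, counts on the
upper triangle (diagonal excluded) follow a log-linear Poisson model with
covariates log(len_i·len_j) and log(gc_i·gc_j) and offset
log(map_i·map_j); the normalized entry divides the observed count by the
fitted systematic part, excluding the intercept so overall scale is
preserved. Mappability defaults to 1 when no track is supplied; GC can be
computed from the genome sequence. Zero-variance covariates (e.g. length
on uniform bins) are dropped with a warning. Trans entries are passed
through unchanged — the model is a cis-bias model.

## Sample comparison

Sample correlation computes, per bin, the Pearson correlation of that
bin's virtual-4C profile (its matrix row) between two samples, then
summarizes over bins by mean or median; constant rows are skipped.

Relative differences (A−B)/((A+B)/2) are bounded by [−2, 2]; entries zero
in both samples are defined as 0 (no evidence of difference) rather than
missing. Correlated differences are row-wise Pearson correlations of the
relative-difference matrix, making coordinated neighbouring changes
visible as blocks.

The signed difference matrix is sign(A−B). Its summary statistic is
|mean sign| over unmasked upper-triangle entries — 0 when gains and losses
balance, 1 when wholly one-sided. Significance is empirical,
p = (k+1)/(n+1). Two nulls are implemented, because the right null depends
on what data exist: with per-sample replicates, replicate labels are
permuted and the statistic recomputed (exact but coarse for few
replicates: with 3 vs 3 the attainable minimum is ~0.1); without
replicates, signs of independent entry blocks are flipped at random. The
default block size is 1 (independent entries), which is calibrated for
exchangeable noise — the p-value distribution is uniform under an i.i.d.
null; for data with spatial correlation a larger block size matching the
correlation length gives a more conservative, more honest test. Both the
statistic and the null construction are deliberately kept behind this one
function so they can be swapped.

## Distance decay and compartments

The IDE is the OLS slope of log10(mean frequency per distance class) on
log10(distance). For binned data the classes are exact bin offsets; for
restriction fragments, midpoint distances are pooled into 50 log-spaced
classes (fits on raw variable-size fragment distances would be dominated
by the dense short-range classes). The default fit range runs from twice
the (median) fragment size — below which self-ligation and digestion
geometry distort counts — to half the longest chromosome, beyond which
classes are sparse. Fewer than three usable classes is an error, not a
silent fit.

Compartment calling follows the classical eigenvector approach: per
chromosome, distance-normalize the intra map, correlate its columns, run
PCA, and split fragments by the sign of the first principal component.
Masked (all-zero) fragments are dropped row-and-column-wise before the
correlation step. Two well-known degeneracies are handled explicitly:

* **Sign ambiguity.** An eigenvector's sign is arbitrary. With an
  orientation track (typically gene counts, higher in the open
  compartment) the FPC is flipped so their correlation is positive;
  without one, the largest-magnitude score is made positive — arbitrary
  but stable across runs.
* **No structure.** A chromosome without compartment structure still has
  a first eigenvector; its variance explained is low and the result is
  flagged (`flag_below`, default 10 %) instead of silently labelling
  noise.

Restriction-fragment matrices should be re-binned to uniform bins before
compartment calling (variable fragment sizes conflate length with
signal); `aggregate_track`/`bin_genome` provide the pieces, and the
compartment tests run on uniform bins.

Track association uses `cor.test` on the FPC (count tracks log2(x+1)
first) or the two-group route: split by FPC sign, report the ratio of
group means, and test with a two-sided Wilcoxon rank-sum test. A zero
denominator with non-zero numerator reports an infinite ratio and is
flagged.

## Balanced region resampling

The interactome depends strongly on linear genomic position, so a fair
null for "are my regions special?" must preserve position covariates.
Each random set mirrors the observed set: one interval per observed
region, of identical length, on the same chromosome, uniformly placed
over all valid starts — and confined to the same region class (e.g.
chromosome arm vs pericentromere) when a class table is supplied. This
chromosome+class matching is the strongest interpretation of "balanced"
that can be tested; a chromosome-only mode remains available. Random
intervals may overlap each other and the observed regions; no exclusion
is applied.

The interaction statistic is the mean frequency over between-region
fragment pairs, *excluding* within-region pairs — the question is whether
regions contact each other, not how dense they are internally. Fragment
membership is by midpoint. The feature statistic aggregates the track
over the regions' fragments with multiplicity (sum for counts,
length-weighted mean for densities), so overlapping random placements
remain comparable to disjoint observed ones. P-values use the
(k+1)/(n+1) rule, guaranteeing p ≥ 1/(n+1) and exact extremes (99 sets,
observed above all nulls: p = 0.01).

## The synthetic-data generator

The generator is first-class code, not a fixture: it plants every
structure the analyses are designed to recover. Contacts are drawn from
P(i,j) ∝ b_i·b_j·ρ^[same block]·d(i,j)^(−α) within chromosomes and a flat
b_i·b_j background between them; defaults are α = 0.85 (a plant-like
decay), block contrast ρ = 2, unit biases and a trans weight of 1e−3.
Genomes plant recognition sites at Poisson spacings (default one per
4 kb, the genome-wide density of a 6-cutter) into random sequence whose
accidental motif occurrences are destroyed by point mutation, so the
expected fragment table is exact. Artefact pairs (short inward/outward)
and MAPQ-0 ends are injected truth-labelled. Tracks differ between
compartments by a configurable multiplicative effect (default 2×), with
methylation elevated in the B-like blocks.

What the generator does **not** emulate — and what passing tests
therefore cannot show: PCR duplicates, mappability holes, copy-number
variation, chimeric/ligation-junction reads, sequencing error, distance-
dependent trans structure, or more than two compartment states. Results
on real data depend on upstream alignment quality in ways these tests do
not probe.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately modest problem
sizes — 60–200 bins per matrix, 2×10⁵–10⁶ simulated pairs, 99–499
permutations, 200 calibration replicates — chosen so each planted
parameter is comfortably identifiable at its stated tolerance (e.g. the
decay exponent to ±0.05 at 10⁶ pairs, ICE bias correlation > 0.99 at 200
bins) while the whole suite runs in a couple of minutes. Degenerate
inputs are errors, not guesses: empty genomes, all-masked matrices,
non-convergent balancing, sub-3-class IDE fits, empty FPC sign groups and
unplaceable regions all fail loudly with the offending object named.
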