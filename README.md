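# hicdesk

Hi-C read pairs report which genomic loci were spatially close in the
nucleus. `hicdesk` takes two files of separately aligned Hi-C read-ends and
turns them into fragment-level contact matrices, attaches genomic and
epigenomic annotation tracks to the same fragment coordinate system, and
provides the higher-level analyses used to describe chromosome organization
as a phenotype: normalization, sample correlation and comparison,
interaction decay exponents, A/B-like compartment calling, and
resampling-based enrichment tests for regions of interest. It is aimed at
researchers who want to compare nuclear architecture between samples
(genotypes, tissues, conditions) without building a pipeline from scratch.

## What it computes

* **Contact matrices.** Read-ends are paired by name (only uniquely aligned
  ends), optionally filtered for close *inward* pairs (uncut DNA) and
  *outward* pairs (self-ligation), located in restriction fragments or
  fixed-size bins, and counted per unordered fragment pair into a symmetric
  sparse matrix.
* **Tracks.** Four per-fragment data types with distinct semantics:
  annotation counts (1 per feature spanning the whole fragment, 0.5 per
  partial overlap), short-read counts (each read counted once at its 5'
  base), coverage densities (percent of bases covered by ≥ 1 element) and
  methylation densities (percent methylated cytosines, pooled). Counts sum
  and densities average (length-weighted) under re-binning.
* **Normalization.** Three methods: observed/expected at each genomic
  distance with coverage normalization of trans contacts; iterative
  correction (ICE), factoring the matrix as *O = B W B* until row sums of
  *W* are equal; and HiCNorm-style Poisson regression of counts on
  log fragment length, GC and mappability products.
* **Sample comparison.** Virtual-4C sample correlation; relative
  differences (A−B)/((A+B)/2); correlated differences; and signed
  difference matrices (SDMs), sign(A−B) with an |mean sign| statistic and a
  permutation p-value.
* **Structure.** The interaction decay exponent (IDE), the slope of
  log10 mean contact frequency against log10 distance; and compartments
  from the sign of the first principal component (FPC) of the correlated,
  distance-normalized intra-chromosomal map, with track-correlation and
  Wilcoxon sign-group enrichment tests.
* **Region tests.** Balanced resampling — random region sets matching the
  observed set in number, length and chromosome (optionally region class) —
  giving one-sided empirical p-values, p = (k+1)/(n+1), for interaction or
  feature enrichment.
* **Synthetic data.** A seed-deterministic generator plants restriction
  sites, a power-law decay exponent, compartment blocks, per-fragment
  biases and compartment-correlated tracks, and emits FASTA/SAM/GFF/TSV
  inputs with exact truth tables, so the whole pipeline is testable without
  external data.

## Worked example

Simulate a two-chromosome genome with planted HindIII sites, draw 200,000
read pairs from a contact model with decay exponent 0.85 and alternating
compartment blocks, then run the full path from SAM files back to biology:

```r
library(hicdesk)

g <- generate_genome(c(chr1 = 500000, chr2 = 300000),
                     site_rate = 1 / 2500, seed = 42)
model <- contact_model(decay_exponent = 0.85, block_contrast = 2,
                       blocks = alternating_blocks(g$fragments, 10))
sim <- simulate_pairs(g$fragments, model, n_pairs = 2e5, seed = 42,
                      dir = "ex")

mat <- pair_alignments(sim$files$forward, sim$files$reverse) |>
  filter_close_pairs(inward_threshold = 1000, outward_threshold = 25000) |>
  count_interactions(g$fragments)
mat
#> <interaction_matrix> 307 fragments, 33503 non-zero pairs, total count 180635

compute_ide(mat)
#> <ide_result> IDE (slope) = -0.7729, intercept = 3.559, R^2 = 0.978
#>   fit over 22 distance classes in [3598, 250000] bp

glance(compartment_fpc(mat))
#> # A tibble: 1 × 6
#>   n_fragments n_a_like n_b_like n_masked mean_var_explained n_flagged_chromosomes
#> 1         307      151      156        0              0.110                     0
```

The IDE (−0.77) is the fitted distance-decay slope; it sits slightly above
the planted −0.85 because the proximity filter removes part of the
short-range signal and restriction fragments have variable sizes. The
compartment call splits the 307 fragments into A-like/B-like groups that
recover the planted blocks for 92 % of fragments here (≥ 95 % on uniform
bins). `filter_close_pairs` removed 7,969 inward and 11,396 outward pairs,
as reported by `pairing_stats(mat)`.

Every result object has `tidy()`/`glance()` methods and an `autoplot()`;
`render_heatmap()` writes contact-map and difference heatmaps to PNG.

A command-line interface over the same functions is installed at
`system.file("cli", "hicdesk.R", package = "hicdesk")` with subcommands
`digest`, `bin`, `pair`, `map`, `tracks`, `normalize`, `correlate`,
`compare`, `ide`, `compartments`, `fpc-enrich`, `regiontest` and
`simulate`.

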