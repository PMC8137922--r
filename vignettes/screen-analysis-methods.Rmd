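---
title: "Methods: analysing single-cell ATAC CRISPR screens with atacscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing single-cell ATAC CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atacscreen)
```

This vignette is the package's account of its models and the decisions
behind them: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and where genuinely open
design choices were resolved.

## The screen and its read-outs

A pooled CRISPRi screen with an accessibility read-out delivers two data
streams per cell: genomic fragments (the scATAC library) and targeted
sgRNA-enrichment reads (a spacer read plus the cell-barcode index read).
Every analysis below reduces to comparing cells carrying a targeting
guide against cells carrying non-targeting (NT) controls from the same
emulsion, which controls for batch, depth and cell-state composition to
the extent the NT cells are representative.

## Guide assignment

Barcode resolution precompiles every single-substitution variant of
every whitelist barcode into one lookup. A variant reachable from two or
more whitelist entries is ambiguous and discarded; a variant that is
itself a whitelist barcode resolves exactly (exact wins over mismatch).
This trades a little yield for specificity: a wrong cell identity
corrupts two cells' profiles, while a dropped read costs only coverage.
Spacer matching is exact and anchored at read position 0, because the
sequencing primer places the spacer at the read start; a scan window
(0–3 bp) and a 1-mismatch mode exist for degraded libraries but are off
by default.

A cell is assigned to its top-count guide when

* `c_total >= 20` — with fewer than ~20 reads the multinomial noise on
  the specificity ratio is too large to trust, and
* `s = c_top / c_total >= 0.8` — lower values indicate barcode collision,
  ambient contamination, or a doublet.

The count threshold applies to the cell's total sgRNA reads, the literal
reading of "at least 20 sgRNA counts"; the specificity is computed per
individual guide (the stricter reading), with an optional mode that sums
guides sharing a target first. Counts are raw reads: the enrichment
library has no UMIs, and PCR duplication inflates numerator and
denominator alike, leaving the scale-free ratio unbiased. Ties for the
top count are never assigned.

## Matrices, QC, and LSI

Fragment files are taken in the 10x dialect: 0-based half-open,
already Tn5-offset corrected, so the two insertion events of a fragment
sit at `start` and `end - 1`. All intervals in the package share that
convention, so BED input needs no shifting. Tile matrices bin insertions
into 500-bp windows (`floor(pos / 500)`); peak matrices count insertions
inside half-open peaks and require a sorted, non-overlapping peak set.

TSS enrichment is the flank-normalised convention: mean per-bp insertion
density within ±50 bp of the nearest TSS over the density in the
1901–2000 bp flanks, one pseudocount in the flank sum. Under a uniform
insertion rate the statistic is ~1; the filter keeps cells with
enrichment ≥ 4 *and* ≥ 1000 fragments. The threshold is only meaningful
relative to the window convention, which is why the convention is fixed
here and stated. Doublets are deliberately not filtered: perturbation
screens form few discrete clusters, so heterotypic doublets are largely
undetectable, and any filter would mostly remove real cells.

LSI binarises the matrix (presence/absence carries most of the signal at
single-cell coverage), weights by `log(1 + tf * 1e4)` term frequency and
`log(1 + n_cells / (1 + feature frequency))` inverse document frequency,
and embeds with a rank-30 truncated SVD. Iterative re-selection of
features (cluster, re-embed) is intentionally not performed: the only
downstream consumer of a global embedding here is visualisation, and the
purity refinement builds its own embedding on differential tiles, so a
single pass on the most accessible features suffices and removes a
dependency on graph clustering. Components whose absolute correlation
with log10 depth exceeds 0.75 are flagged but not dropped by default —
dropping is a visible configuration switch, so the decision is
reproducible rather than silent. For numerical determinism the truncated
SVD uses a fixed (non-random) start vector and component signs are
standardised on the largest loading; reruns are byte-identical.

## Bias-corrected motif deviations

For cell *i* with total `T_i` and motif peak set `S`, expected counts
are `e = T_i * sum_{p in S} f_p`, where `f_p` is peak *p*'s share of all
counts; the raw deviation is `Y = (o - e) / e`. Raw deviations confound
motif biology with GC composition and mean accessibility, so each peak
draws 50 background peaks from its own bin of a 25×25 grid on the
standardised (GC, log1p mean accessibility) plane. Binned sampling was
chosen over nearest-neighbour sampling because it is simpler, exactly
reproducible given a seed, and the contract is only "a bias-matched
null", not a particular sampler. The corrected deviation subtracts the
background mean; the z-score divides by the background standard
deviation (sample sd over the 50 iterations). Degenerate cases are
explicit: motifs with no matching peaks, zero expectations, and
zero-variance backgrounds yield `NA` and a flag, never a silent zero.
Averaging across a perturbation's cells uses corrected deviations;
rank-based differential testing uses z-scores.

## Purity refinement

Misassigned cells (ambient sgRNA, collisions) dilute every downstream
contrast. For each target, tiles are ranked by pseudobulk log2 fold
change against NT (pseudocount 1 on profiles scaled to 10^6), keeping
only tiles whose sign is reproduced by *every* individual guide of the
target — "reproducibly regulated" operationalised as sign consistency,
the weakest defensible reading that still suppresses guide-specific
artefacts. The top 5000 rising and 5000 falling tiles (ties broken by
absolute scaled difference, then tile index) feed an LSI embedding of
the target-plus-NT cells; each target cell's PurityRatio is the fraction
of its 20 nearest neighbours (cosine distance in the 30-dimensional LSI
space, self excluded) assigned to the target, and assignments survive
only above 0.9 (strict). Neighbourhoods are computed in LSI space rather
than in a 2-D projection because planar embeddings distort
neighbourhoods; a UMAP is for looking at, not for measuring. NT cells
are never purity-filtered — they define the reference and the quoted
procedure filters targeting cells only.

## Perturbation scoring and differential tests

The perturbation score is the mean corrected deviation of a target's
cells minus the NT mean, per motif, ranked by absolute value. Motif
collections are redundant, so within each motif family only the member
with the highest deviation variability (sd of z across cells) is kept,
ties resolved lexicographically. Across screens, a motif's score is the
mean over screens of its per-screen maximum |delta| across targets.
Outlying NT guides can be excluded via an explicit configuration list
after pseudobulk PCA review — exclusion is a judgement call and is kept
visible as configuration, never automated.

Differential motifs use a two-sided Wilcoxon rank-sum test on deviation
z-scores with the normal approximation and tie correction. The test is
computed in-package (rather than calling `wilcox.test`) for one reason:
a defined degenerate behaviour — an all-tied comparison sits at the null
centre with p = 1 instead of NaN; on non-degenerate data it agrees with
`wilcox.test(exact = FALSE, correct = FALSE)` to machine precision (a
test asserts this). Controls are depth-matched greedily within a
[0.95, 1/0.95] depth-ratio window and each side is subsampled to at most
250 cells under the caller's seed.

Peak-level differential accessibility uses the exact conditional
binomial test: at each peak with target counts `k` and control counts
`m`, `k ~ Binomial(k + m, n / (n + b))` under the null, with `n`, `b`
the group grand totals. Conditioning on the peak total is the standard
exact two-sample Poisson comparison; treating an estimated control rate
as a fixed null probability would double the variance of the test
statistic with equal-sized groups and inflate type-I error severalfold,
which the calibration tests would (and in development did) expose.
Thresholds default to |log2FC| > 0.5 and FDR < 0.1, with the stricter
FDR < 0.05 used by some displays available by argument. Time-course
analyses take the union of peaks strong (|log2FC| > 1) at any timepoint
and keep those above 0.25 somewhere, so transient and sustained
responses both survive. Peak modules come from k-means (10 restarts,
best within-cluster SS, fixed seed) on row-z-scored log2 pseudobulk;
motif enrichment per module is an upper-tail hypergeometric test against
the tested-peak universe, BH-corrected.

## Network rewiring

For cells of one perturbation and the NT cells separately, all pairwise
Pearson correlations between de-duplicated motif deviations are
computed; their difference (targeting minus NT) highlights co-variation
created or destroyed by the perturbation. Pearson on corrected
deviations is the default because deviations are approximately
continuous and symmetric at screen depths; Spearman is available by
argument. The difference matrix is clustered with complete-linkage
hierarchical clustering on Euclidean row distances and cut into five
modules — the defaults of the standard clustering calls, recorded in the
output attributes.

## The synthetic generator

The generator emulates exactly the statistical structure the pipeline
assumes: per-cell sgRNA reads (log-normal depth, median ~80) carrying
the true spacer with probability `1 - contamination` (default 0.05) and
a random other spacer otherwise, with per-base substitution errors
(default 0.002) on both reads; and accessibility counts
`X_ip ~ Poisson(d_i * lambda_p * e_ip)` with log-normal cell depths,
Gamma-distributed peak baselines (mean 0.1 counts per unit depth — tile
matrices are sparse, and sparsity is what LSI's binarisation responds
to), and fold-change `e_ip` injected when cell *i*'s target perturbs a
motif containing peak *p*. Defaults describe a desk-scale screen: 12
targets × 2 guides + 3 NT guides, 100 cells per guide (200 per target
arm), 2000 peaks, 20 motifs of 50 peaks, effect ×2 — target *i* on motif
*i*. GC is drawn independently of effects so background matching cannot
absorb true signal; a confounded mode exists to demonstrate why the
matching matters. Poisson counts are the default (sparse insertion
counts are near-Poisson at these depths) with a Gamma–Poisson
overdispersion switch for robustness checks. Everything is driven by one
mandatory seed; FASTQ output is byte-identical across reruns.

What the generator does *not* emulate: genomic sequence, fragment-length
structure, cluster-rich cell-state heterogeneity, batch effects, or
motif co-occurrence along the genome. Passing tests therefore certify
the algorithms' correctness and calibration under the stated model, not
performance on any particular real screen.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale problems chosen to make each
property measurable with headroom: the recovery screen at the full
12 × 200-cells-per-arm design with 2000 peaks and 50 background
iterations; purity simulations at 120–300 cells per arm over 120 tiles;
calibration at 200 null replicates of 200 peaks × 200 cells (binomial)
and 200 replicates × 10 motifs (rank-sum). Tolerances: the deviation
engine must agree with a brute-force evaluation of its defining formula
to 1e-10; hypergeometric p-values with exact combinatorics to 1e-12;
type-I error bands are [0.03, 0.07] at nominal 0.05.

Known limitations: assignment below ~20 reads per cell is noise-limited
by design; the purity step assumes the perturbation moves accessibility
enough to separate target from NT cells (a null perturbation loses most
of its cells, which is the intended behaviour, not a defect); the
conditional binomial test shares the usual caveat that pseudobulk
conditioning ignores cell-level overdispersion, which is why the
rank-sum path on per-cell z-scores is the default for motif-level
conclusions.
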