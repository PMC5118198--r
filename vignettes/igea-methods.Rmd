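---
title: "Methods: gene set x brain circuit enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene set x brain circuit enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain-wide GWAS associates every SNP with every imaging quantitative
trait (QT), typically one per brain ROI. After collapsing SNPs to genes,
the findings form a gene x QT grid. `igea` tests a two-dimensional
hypothesis on that grid: is the block defined by a gene set (GS) and a
brain circuit (BC) over-represented among the significant gene-QT pairs?
Candidate GS-BC pairs are derived from a reference gene x ROI expression
matrix, on the premise that genes (or ROIs) with shared expression
profiles form meaningful functional units.

## Model and procedure

**Gene scoring.** The gene-level p-value for a QT is the minimum SNP
p-value inside the closed window `[max(1, start - w), end + w]`, with
`w = 20000` bp by default. The minimum-p rule is simple and widely used;
it is anti-conservative for long genes with many SNPs, and no SNP-count
correction (VEGAS/GATES style) is applied - scores should be compared
across analyses with that caveat in mind. Windows are symmetric and
strand is ignored. Boundaries are inclusive, so tests can be bit-exact.
Genes with no in-window SNP for any QT are dropped; a gene covered for
some QTs only receives filler p = 1 elsewhere, keeping the universe a
complete `N_G x N_B` grid, which the enrichment arithmetic assumes.
Significance at threshold `t` (default `1e-5`) uses strict `p < t`.

**Module construction.** Expression preprocessing merges samples to ROIs
and probes to genes by arithmetic means, then standardizes each ROI
column to mean 0, sd 1. The population sd (divisor `n`) is used: the
column is treated as the complete profile over the measured genes, not a
sample from a larger one; constant columns are zeroed and flagged rather
than dropped, so column indices stay aligned. Dissimilarities are
`d = (1 - corr)/2`, mapping the correlation range [-1, 1] onto [0, 1].
Both axes are clustered with UPGMA (average linkage), whose heights are
monotone, and each dendrogram is cut at half of its root height - the
natural scale-free reading of "half of the tree's height". Cluster
membership at the cutoff is inclusive (`height <= cutoff`). Gene
clusters of size 10-200 (the conventional pathway-size band) become gene
sets; ROI clusters of size >= 2 become circuits - the ROI-based score is
an average over column pairs, so a single-ROI circuit has no score.

**Module scores.** Within a module submatrix X, all pairwise
correlations along one axis are Fisher z-transformed
(`z(c) = atanh(c)`) and averaged: `z_gene` over gene-row pairs
(computed on the module's ROIs only) and `z_roi` over ROI-column pairs
(on the module's genes only). Fisher z diverges at `|c| = 1`, so
correlations are clamped to `1 - 1e-12` in magnitude first; the clamp
keeps scores finite and order-preserving (an exactly duplicated profile
scores ~14.2, far above any noisy correlation, which is the intended
ranking). Zero-variance profiles get correlation 0 with a warning
rather than NaN. Modules are ranked by each score and the top
`ceiling(fraction * M)` kept (`fraction = 0.2`); the ceiling makes the
count well-defined for any M, and boundary ties break by module id so
selection is deterministic. The `gene_and_roi` strategy is the
intersection of the two selections.

**Enrichment.** For a module with gene set `G_k` and circuit `B_k`, the
testable block is `T = (G_d ∩ G_k) x (B_d ∩ B_k)` inside the universe
`G_d x B_d`; with `m = |T|` and `k` significant pairs inside T, the
p-value is the hypergeometric upper tail `P(X >= k)` (including `k`
itself), computed via the survival function. Bonferroni correction
multiplies by the number of *testable* modules in the current strategy
set and caps at 1; untestable modules (empty axis intersection) carry no
information and are excluded from the correction count, reported with
p = 1. A `correction_scope = "union"` option corrects instead by the
union of the three strategy sets, for users who view the three analyses
as one family.

**Permutation evaluation.** The observed proportion of significant
modules is compared with `n_perm = 50` permuted analyses through
`t = (Prop_orig - mu) / (sqrt(1 + 1/n) * sd)` and a one-sided Student-t
tail with `n - 1` degrees of freedom; the `sqrt(1 + 1/n)` factor is the
prediction-interval inflation for judging one new draw against a sample.
The sample sd (divisor `n - 1`) is used. If all permuted proportions are
equal the statistic is undefined and the function refuses rather than
fabricating a p-value. The default null permutes the assignment of gene
labels to p-value rows: rows travel as units, preserving each gene's
co-occurrence pattern across QTs while breaking the gene-to-module
correspondence. This is a deliberately conservative, structure-preserving
null - a module aligned with strongly hit QT columns can remain
significant under row shuffles whenever several hit rows land inside its
gene set, so the evaluation is sensitive to the *concentration* of
signal in particular gene sets, not to the mere existence of hit
columns. The sparser the hit rows relative to the genome, the sharper
the test; with very few candidate modules the proportion is coarse
(0 or 1 for a single module) and the t approximation is weak. A
`mode = "columns"` alternative permutes each QT column independently,
destroying row structure as well and giving a more liberal null.

## The synthetic test bed

`synthetic_spec()` + `simulate_*()` generate all inputs with known
ground truth. Expression backgrounds are i.i.d. standard normal. Each
planted block is a two-sided latent-factor construct: the block's genes
share a latent profile over **all** ROIs with loading `sqrt(rho)`, and
the block's ROIs share a latent profile over **all** genes with the same
loading; residual sd is reduced to match, floored at `sqrt(0.05)` where
the two factors overlap. This design was chosen over a one-sided factor
(genes sharing a profile over the block's ROIs only) because the method
clusters each axis on *full-axis* profiles: structure confined to a
small sub-block is invisible to global clustering, and a generator
planting only such local structure could never be recovered by the
procedure it is meant to exercise - mirroring the known limitation that
global biclustering misses local co-expression patterns. Within a block
the realized gene-gene correlation across the block's ROIs is
approximately `rho` (at `rho = 0.9`, about `0.9/0.95 ≈ 0.95` after the
residual floor), which the moment-check tests bracket with [0.75, 0.98].

Gene x QT p-values are Uniform(0,1) in the background and Beta(a, 1)
with `a <= 1` inside planted blocks, so the block significance rate at
threshold t is exactly `t^a`. SNP-level simulation lays genes 100 kb
apart on one chromosome (windows never overlap), draws 1-10 SNPs per
gene inside the +/-20 kb window plus a decoy exactly 1 bp outside, and
constrains per-SNP p-values so the in-window minimum reproduces the
gene-level target exactly - making the window rule testable bit-for-bit.

What the generator does *not* emulate: linkage disequilibrium and
realistic minor-allele spectra, spatial correlation of imaging noise,
multi-donor expression variability, and local (sub-block) co-expression.
Passing tests therefore demonstrate the correctness and calibration of
the pipeline's statistics under a clean block model, not performance on
real atlas or cohort data.

## Problem sizes and study conditions used in the tests

The planted-recovery condition is 200 genes x 30 ROIs x 30 QTs with one
20-gene x 6-ROI block at `rho = 0.9`, an aligned p-value block at
`a = 0.05`, and threshold `1e-3`; recovery (a Bonferroni-significant
module with Jaccard >= 0.8 to the planted memberships on both axes) is
required in at least 18 of 20 seeds. The null condition keeps the
co-expression block but draws all p-values uniform, requiring zero
significant modules in at least 19 of 20 seeds, plus a raw-p
false-positive rate within `alpha + 3*SE` over 1000 random module tests.
Permutation calibration treats a permuted matrix as observed on a
richer fixture (four blocks, two enriched, 240 x 40) over 200
repetitions, requiring at most 10% of p-values below 0.05; the
end-to-end detection fixture uses a 2000-gene genome with four planted
modules at `a = 0.3`, where the diffuse per-cell signal cannot be
reconstituted by scattered rows under the row-shuffle null. These sizes
keep every property statistically sharp at desk scale; the published
application-scale counts (a 16,076 x 105 universe, 171 x 9 = 1539
candidate modules, 308 selected at 20%) are exercised directly as
arithmetic through the same code paths.

## Known limitations

- The minimum-p gene score favours long, SNP-dense genes; set-based
  gene scores are out of scope.
- Threshold-based enrichment discards association strength below/above
  the cutoff; no rank-based (GSEA-style) two-dimensional variant is
  provided.
- Only UPGMA with the half-height cut is implemented; other linkages or
  co-clustering algorithms that capture local patterns are not.
- The row-shuffle permutation null is conservative by design (see
  above); with few modules its t approximation is coarse.
- A single expression matrix is consumed; multi-donor harmonization is
  the caller's responsibility.
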