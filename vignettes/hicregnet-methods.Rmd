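---
title: "Methods: from 1D epigenomes to contact maps, loops, and variant subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 1D epigenomes to contact maps, loops, and variant subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicregnet)
library(dplyr)
```

hicregnet implements a pipeline for regulatory genomics in cell types where
high-resolution Hi-C is unavailable: predict 5 kb contact counts from 1D
epigenomic signals with locally trained random forests, call significant
long-range interactions against a distance-matched binomial background,
link non-coding variants to genes through those interactions, and propagate
the variant signal over cell-type-specific molecular networks to find the
gene subnetworks — conserved or cell-type-switching — that the variants
target. This vignette explains each model, its assumptions, and the design
choices made where a choice was genuinely open.

## Coordinate conventions

All genomic coordinates are 0-based half-open (the BED/bedGraph native
convention); a position `p` belongs to bin `floor(p / 5000)`. Contact
matrices are stored as upper-triangular pair tables (`bin1 < bin2`) with
real-valued counts, since both normalized and predicted counts are
non-integer. Candidate pairs span 1–200 bins (5 kb – 1 Mb), and the local
regression models tile the genome in fixed, non-overlapping 1 Mb segments
`[k·1Mb, (k+1)·1Mb)`.

## Local contact-count regression

A separate random-forest regression is trained for every 1 Mb segment on
all pairs with at least one anchor inside the segment; a pair spanning two
segments is predicted by the arithmetic mean of the two forests, and
negative predictions are clamped at zero. Training locally lets each model
absorb regional count regimes (compartment shifts, coverage waves) that no
1D feature encodes, which is exactly where a single chromosome-wide forest
fails — the package's global baseline exists to make that contrast
measurable, and the transfer-count baseline (copy the training cell type's
counts) marks the floor that any cross-cell-type predictor must beat.

Each pair is represented by 31 features: 10 per anchor (7 ChIP/DNase
signals discretized to 20 levels by 1-D k-means, plus 3 motif-hit counts at
PIQ purity > 0.5), 10 window features over the intervening bins, and the
genomic distance in bp. Discretization centers are fitted once on the
training cell type and applied unchanged to every test cell type, which
guarantees level comparability without refitting drift. Window features
average the *discrete* levels for ChIP tracks (the continuous alternative
is available via `apply_discretization` order) and divide total motif
counts by the window width; adjacent pairs, which have no intervening bin,
use the mean of the two anchor values — the continuous limit of the window
definition. Distance stays in raw bp: the forest splits on it freely.

Forest hyperparameters are not dictated by the method: the defaults are 100
trees, `ceiling(p/3)` features per split, unlimited depth, all recorded in
the ensemble metadata. Determinism comes from single-threaded training with
a per-segment derived seed.

## Calling significant interactions

Within each distance stratum `d` (one per 5 kb separation up to 1 Mb) the
null model is uniform: each of the `n_d` observed interaction events falls
on any of the stratum's candidate pairs with equal probability
`m_d = 1/#candidates`. A pair observed `k` times gets the upper binomial
tail `P(K >= k | n_d, m_d)`; Benjamini–Hochberg is applied within the
stratum and pairs with `q < 0.05` are called. Three choices deserve note:

* Predicted counts are real-valued; they are rounded half-to-even before
  testing because the binomial likelihood needs integer counts and this
  rounding is total-preserving on average.
* The candidate universe per stratum is *all* bin pairs at that distance,
  not just the observed ones — zero counts are evidence, not missingness.
* BH is applied per stratum by default (each stratum is its own family,
  matching the per-stratum null); `global_fdr = TRUE` pools across strata.
  The controlled quantity is therefore the per-stratum false discovery
  proportion, which is what the package's null-calibration checks measure.

## TAD calling and comparison

The directionality index of a bin contrasts upstream (A) and downstream
(B) contact mass within 2 Mb: `DI = sign(B-A) * ((A-E)^2 + (B-E)^2)/E`,
`E = (A+B)/2`, zero when `A = B` or `E = 0`, with truncated windows at
chromosome edges. Domains are segmented at sign transitions from a
negative run to a positive run, both of length >= 3 bins — a deterministic,
parameter-light rule that recovers planted blocks exactly at zero noise;
an HMM segmentation is out of scope, and the reciprocal best-match Jaccard
comparison used to compare TAD sets is insensitive to the segmentation
variant as long as both matrices are segmented the same way.

## Variant-to-gene linking and node scoring

A gene claims every bin overlapping its TSS window `[tss-2500, tss+2500)`;
a SNP sits in the bin of its position. Each (SNP bin, gene bin) pair that
is a significant interaction yields a SNP–gene link carrying the loop's
q-value. A gene's score is the mean of `-log10(q)` over its links (q
clamped at 1e-300); scored genes are the *direct hits*. Log base 10 is a
convention — the base only rescales diffusion inputs uniformly. Distinct
(SNP, gene) pairs contribute once, de-duplicated to their smallest q.

## Network assembly and diffusion

Cell-type networks merge three unweighted undirected edge classes: a
high-confidence PPI backbone (score strictly > 0.95), proximal TF–gene
edges (accessible motif with purity > 0.9 in the promoter window), and
distal TF–gene edges (motif in the distal anchor of a significant loop
whose other anchor holds the TSS; a motif in the TSS anchor itself is
proximal territory). Within each TF class, edges are ranked by best motif
purity and the top 5% retained; ties at the cutoff are all kept, since
dropping ties would be an arbitrary order dependence.

Diffusion is two-step. Node diffusion spreads the direct-hit scores with
the regularized Laplacian kernel `V = (I + λL)^{-1} Q`, `L` the symmetric
normalized Laplacian; `λ = 1` by default, selectable on a
`{0.1, 0.5, 1, 5, 10}` grid by leave-one-out AUROC over direct hits (ties
resolve to the smaller λ). Edge diffusion then reweights connectivity with
the insulated heat kernel `K_H = β(I − (1−β)W)^{-1}` (`W = AD^{-1}`,
`β = 0.3`) and forms `H = K_H · diag(V)`. Both kernels are computed by
linear solves, never explicit inverses; degree-zero nodes get zero entries
in `D^{-1/2}` and an identity transition column, which keeps both kernels
well-defined and lets isolated nodes retain their own score. The rationale
for diffusing nodes before edges is the small number of direct hits: edge
diffusion from raw scores alone concentrates weight on too few rows for
stable clustering.

The direct hits plus the top 1% of diffused scores (ties included) are
selected; the selected submatrix of `H` gives each gene a diffusion state
(its restricted row — full rows are available by flag), pairwise L1
distances form the diffusion-state distance matrix `P`, and
`S = exp(−P² / 2σ_P²)` with `σ_P` the population standard deviation of all
entries of `P` converts distance to similarity. `P` is a genuine metric
(the package checks symmetry, zero diagonal and the triangle inequality on
random instances) and `S ∈ (0,1]` with unit diagonal.

## Tree-guided multi-task clustering

Each cell type's `S` is embedded with the k smallest eigenvectors of the
regularized Laplacian `L_τ = I − D_τ^{-1/2} A D_τ^{-1/2}`,
`D_τ = D + mean(D)`, rows normalized to unit length. The original
multi-task algorithm's joint objective is not restated in the sources this
package follows, so hicregnet implements a tree-guided variant that
reproduces its two operational contracts — per-cell-type spectral
clustering on `L_τ`, and cluster identities matched across cell types —
by (1) aligning every cell type's embedding to a leaf-averaged reference
embedding with orthogonal Procrustes, and (2) clustering root-to-leaf
along the cell-type tree, warm-starting each node's k-means from its
parent's centroids (the root runs 50 seeded k-means++ restarts; child
nodes use the single warm start precisely so the correspondence is never
re-randomized). Empty clusters during warm-started Lloyd iterations keep
their previous centroid rather than being reseeded, again to preserve the
index correspondence.

The cluster count is chosen on a `{6..9}` grid by average Newman modularity
of the partitions on the similarity-weighted graphs, subject to a minimum
cluster size (default 5); the cell-type tree comes from UPGMA on Euclidean
distances between promoter H3K4me3 profiles, with an interaction-F-score
tree available as a cross-check (compared via the Fowlkes–Mallows index
with a permutation null).

Gene sets are read off the label matrix by hierarchical clustering of
label vectors under Hamming-fraction distance, cut at 0.1 — i.e. genes in
one set disagree in at most 10% of cell types — with sets under 5 genes
dropped. The cut is on the normalized (fraction) scale because the Hamming
fraction is bounded in [0,1]; optimal leaf ordering affects only display
and not the flat cut, so it is omitted. A set is *conserved* when every
member keeps a single label everywhere, *transitioning* otherwise.
Enrichment of each cluster uses the upper hypergeometric tail against the
phenotype background with BH correction, and the terms × gene-lists
`-log p` matrix is summarized by rank-7 NMF (multiplicative updates,
seeded, fixed iteration cap) whose explained variance
`1 − var(x − x̂)/var(x)` is reported alongside top terms and columns. The
NMF is written in-package; its multiplicative-update form is the standard
Frobenius variant.

## What the synthetic generators emulate

Every stage is validated against generators that plant known structure:

* **Contact matrices** follow `base · d^{−α} · (1 + boost · same-block) ·
  exp(ε)` with log-normal noise (counts stay positive and heavy-tailed,
  as in real Hi-C) over random contiguous TAD blocks; defaults are 600
  bins (3 Mb), 6 blocks, α = 1, boost = 1, noise sd 0.2.
* **Signal panels** carry the count-generating structure in two tracks —
  a per-block accessibility level (block identity, in per-cell-type random
  order so the value itself encodes no genomic position) and
  boundary-flanking CTCF motif clusters (peaks on the last bin of one
  block and the first of the next, so any window crossing a boundary
  contains a peak) — plus spatially iid nuisance tracks. The iid choice is
  deliberate: spatially smooth nuisance signal shared across cell types
  would let a forest memorize the training cell type's block layout by
  position, which is exactly the failure mode cross-cell-type prediction
  must not reward.
* **Segment regimes** (`segment_effect_sd`) add a deterministic per-1Mb
  log-scale count ramp shared across cell types but absent from every
  feature, creating the piecewise generative setting in which the local
  ensemble demonstrably beats the global forest.
* **Multi-cell-type networks** are stochastic block models (within 0.25,
  between 0.02) over shared modules; half of each transitioning module
  moves as a block into another module within one clade of an ultrametric
  two-clade cell-type tree, so every module stays non-empty everywhere and
  the planted transition is structurally detectable.
* **SNP studies** place a chosen fraction of SNPs into loop anchors whose
  partner holds a TSS and emit a chosen subfraction of the implied
  SNP–gene links as eQTL pairs, making precision/recall computable from
  the plant alone.

These generators reproduce the statistical structure the methods assume —
distance decay, block enrichment, feature–count coupling, module structure
— not biological realism: no sequence, no replicate structure, no
assay-specific noise. Passing tests therefore demonstrate method
correctness and recoverability under the stated model, not performance on
real tissue.

## Problem sizes and numerical choices

Validation runs use 400–600 bin chromosomes (2–3 Mb), 25–50 tree forests
on 20–30% pair subsamples, 300-gene networks and 3 cell types — sizes
chosen so the full property suite completes in minutes on one core while
leaving every distance stratum and module populated. Key tolerances:
binomial tails match a log-space summation oracle to 1e-10 (n ≤ 1000);
kernel solves satisfy residual norms below 1e-10 and match dense-inverse
oracles to 1e-8 (n ≤ 200); q-values are clamped at 1e-300 before logs;
k-means discretization reduces k to the number of distinct values on
degenerate tracks; midpoint ties in level assignment go to the lower
level; the top-fraction and top-percent selections keep ties at the
cutoff.

## Known limitations

Single-chromosome orientation (multi-chromosome analyses loop over
chromosomes); no .hic/.cool readers (pairs TSV only); no HMM TAD
segmentation or nested domains; LD expansion, motif scanning and signal
imputation are consumed as inputs, not computed; the multi-task clustering
is a documented variant, not a re-derivation of the published joint
optimization; and the directed nature of TF→gene edges is deliberately
ignored because the diffusion kernels are symmetric.
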