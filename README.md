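# hicregnet

Most cell types and tissues have rich 1D epigenomic profiles (histone
marks, chromatin accessibility) but no high-resolution Hi-C. hicregnet is
an R package for regulatory genomicists who want to work with 3D genome
organization in exactly those cell types: it predicts 5 kb Hi-C contact
counts from 1D signals, calls significant long-range interactions and
TADs on the predicted maps, links non-coding GWAS variants to target genes
through those interactions, and propagates the variant signal over
cell-type-specific molecular networks to identify the gene subnetworks —
conserved across cell types or switching between them — that the variants
impinge on.

## The methods in brief

**Local contact regression.** The chromosome is tiled into non-overlapping
1 Mb segments; a random-forest regression is trained per segment on all
5 kb pairs touching it, each pair represented by 31 features (10 per
anchor: 7 k-means-discretized ChIP/DNase levels + 3 motif counts at PIQ
purity > 0.5; 10 window features over the intervening bins; genomic
distance). A pair spanning two segments is predicted by the mean of the
two forests. Baselines: a single chromosome-wide forest, and the
transfer-count baseline (copy the training cell type's counts).

**Loop calling.** Within each 5 kb distance stratum *d* up to 1 Mb, a pair
observed *k* times is tested against Binomial(*n_d*, *m_d*) with *m_d* the
uniform per-pair probability and *n_d* the stratum total, i.e. the upper
tail ∑_{i≥k} C(n,i) m^i (1−m)^{n−i}; BH correction within the stratum,
calls at q < 0.05.

**TADs.** Directionality index DI = sign(B−A)·((A−E)²/E + (B−E)²/E) over
2 Mb windows, segmented at sustained negative-to-positive sign
transitions; TAD sets are compared by reciprocal best-match base-pair
Jaccard.

**Variants to subnetworks.** SNPs map to genes when their bins form a
significant loop with a TSS window (±2500 bp); gene scores are mean
−log10(q) over a gene's SNP loops ("direct hits"). Scores diffuse over a
merged PPI + proximal + distal TF–gene network with the regularized
Laplacian kernel V = (I+λL)⁻¹Q (λ = 1, LOO-CV selectable), edges reweight
with the insulated heat kernel K_H = β(I−(1−β)W)⁻¹ (β = 0.3),
H = K_H·diag(V); the selected submatrix becomes a diffusion-state distance
(L1 between rows) and a Gaussian similarity S = exp(−P²/2σ_P²).

**Multi-task clustering.** Per cell type, spectral embedding of S with the
regularized Laplacian L_τ = I − D_τ^{-1/2} A D_τ^{-1/2} (D_τ = D + mean D);
embeddings are Procrustes-aligned to a reference and clustered root-to-leaf
along the cell-type tree (UPGMA on promoter H3K4me3) with warm-started
k-means, so cluster *c* means the same thing in every cell type. Gene sets
cut from the label matrix at Hamming-fraction 0.1 (min 5 genes) are flagged
conserved or transitioning; per-cluster hypergeometric enrichment is
summarized by rank-7 NMF.

Every stage ships with a synthetic-data generator that plants ground truth
(TAD blocks with distance decay, signal panels whose features generate the
counts, stochastic-block-model networks with transitioning modules, SNP
studies with known links), so the whole pipeline is testable end to end.

## Worked example

Train on one simulated cell type, predict a second, and push the
predictions through loops, TADs and SNP linking:

```r
library(hicregnet)
library(dplyr)

spec_train <- synthetic_spec(n_bins = 400, noise_sd = 0.2,
                             segment_effect_sd = 0.6, seed = 1)
spec_test  <- synthetic_spec(n_bins = 400, noise_sd = 0.2,
                             segment_effect_sd = 0.6, seed = 2)
train_cm <- synth_contact_matrix(spec_train)
test_cm  <- synth_contact_matrix(spec_test)
train_panel <- synth_signal_panel(spec_train, train_cm)
test_panel  <- synth_signal_panel(spec_test, test_cm)

# discretization is fitted on the training cell type and applied everywhere
models <- lapply(train_panel$chip, fit_discretization, k = 20, seed = 1)
featurize <- function(panel, cm) {
  levels <- mapply(apply_discretization, models, panel$chip, SIMPLIFY = FALSE)
  build_pair_features(levels, panel$motif, n_bins = 400) |>
    add_counts(cm$contacts)
}

ensemble <- train_local(featurize(train_panel, train_cm), trees = 50, seed = 1)
ensemble
#> <lhicreg_ensemble> local ensemble (2 segments of 200 bins), 50 trees, mtry 11

pred <- predict_counts(ensemble, featurize(test_panel, test_cm))
stratified_correlation_auc(pred, test_cm$contacts, n_bins = 400)
#> <distance_correlation> AUC = 0.8303 over 200 strata

# the transfer-count baseline on the same task
transfer <- baseline_transfer_count(train_cm$contacts, test_cm$contacts)
glance(stratified_correlation_auc(transfer, test_cm$contacts, n_bins = 400))$auc
#> [1] 0.8200189

loops <- call_loops(pred, n_bins = 400)
nrow(loops)
#> [1] 4859

tads_pred <- call_tads(directionality_index(pred, n_bins = 400))
tads_true <- call_tads(directionality_index(test_cm$contacts, n_bins = 400))
tad_jaccard_similarity(tads_pred, tads_true)
#> [1] 0.5191338

study <- synth_snp_study(spec_test, loops, n_snps = 30)
pairs <- link_snps_to_genes(study$snps, loops, study$tss)
head(score_genes(pairs), 3)
#> # A tibble: 3 × 4
#>   gene_id score direct_hit n_snps
#>   <chr>   <dbl> <lgl>       <int>
#> 1 gene006  2.44 TRUE           11
#> 2 gene007  2.23 TRUE           12
#> 3 gene008  2.34 TRUE           12
```

The distance-stratified AUC is the mean Pearson correlation between
predicted and measured counts across 5 kb distance strata: 0.83 here, just
above the transfer baseline because the simulated segment regimes are
shared between cell types — the local/global contrast is sharper (see the
reproduction script below). A gene's score of 2.4 means its supporting
loops have q ≈ 10⁻²·⁴ on average; such direct hits seed the network
diffusion (`diffuse_network()`) and multi-task clustering
(`multitask_cluster()`, `transitioning_gene_sets()`).

A thin command-line wrapper over the same functions is installed at
`inst/cli/hicregnet.R` with `simulate`, `callloops`, `calltads` and
`evaluate` subcommands.

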