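# Synthetic-data generators. Every downstream stage (regression, loop
# calling, TAD calling, SNP linking, diffusion, multi-task clustering) gets a
# generator that plants known structure and returns the ground truth next to
# the data, so accuracy metrics can be computed without re-deriving anything.

#' Specification for the synthetic study
#'
#' Collects every knob of the synthetic generators in one place. All
#' generators are pure functions of the spec (including its seed).
#'
#' @param n_bins Number of 5 kb bins on the simulated chromosome (>= 400 so
#'   the full 1 Mb pair span exists). Default 600 (3 Mb).
#' @param n_tads Number of planted TAD blocks. Default 6.
#' @param base Baseline contact count at distance one bin. Default 100.
#' @param decay_exponent Power-law exponent of contact decay with distance
#'   (counts ~ distance^-decay_exponent). Default 1.
#' @param tad_boost Multiplicative within-TAD contact enrichment; a pair in
#'   the same planted block gets `(1 + tad_boost)` times the background.
#'   Default 1.
#' @param noise_sd Standard deviation of log-normal multiplicative count
#'   noise. Default 0.2.
#' @param segment_effect_sd Amplitude of a per-1Mb-segment log-scale count
#'   effect that is a function of genomic position only (not of any signal
#'   feature). 0 (default) disables it; a positive value spreads the
#'   segments' log effects evenly over `segment_effect_sd * [-1.5, 1.5]`,
#'   creating segment-specific count regimes that are shared across cell
#'   types (they belong to the locus) but that no signal feature encodes, so
#'   a single chromosome-wide model cannot represent them.
#' @param n_cell_types Number of simulated cell types for the network stage.
#'   Default 3.
#' @param n_genes Number of genes in the simulated networks. Default 300.
#' @param n_modules Number of planted network modules. Default 6.
#' @param n_transitioning Number of planted modules that switch membership in
#'   a designated subtree of the cell-type tree. Default 1.
#' @param p_within,p_between Stochastic-block-model edge probabilities within
#'   and between modules. Defaults 0.25 and 0.02.
#' @param snp_linked_frac Fraction of simulated SNPs planted inside loop
#'   anchors whose partner anchor holds a TSS. Default 0.8.
#' @param eqtl_frac Fraction of planted SNP-gene links that are also emitted
#'   as eQTL pairs. Default 0.5.
#' @param seed Integer seed; fully determines all generator output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 600L, n_tads = 6L, base = 100,
                           decay_exponent = 1, tad_boost = 1, noise_sd = 0.2,
                           segment_effect_sd = 0, n_cell_types = 3L,
                           n_genes = 300L, n_modules = 6L,
                           n_transitioning = 1L, p_within = 0.25,
                           p_between = 0.02, snp_linked_frac = 0.8,
                           eqtl_frac = 0.5, seed = 1L) {
  spec <- list(n_bins = as.integer(n_bins), n_tads = as.integer(n_tads),
               base = base, decay_exponent = decay_exponent,
               tad_boost = tad_boost, noise_sd = noise_sd,
               segment_effect_sd = segment_effect_sd,
               n_cell_types = as.integer(n_cell_types),
               n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
               n_transitioning = as.integer(n_transitioning),
               p_within = p_within, p_between = p_between,
               snp_linked_frac = snp_linked_frac, eqtl_frac = eqtl_frac,
               seed = as.integer(seed))
  structure(spec, class = "synthetic_spec")
}

# Random TAD layout: n_tads contiguous blocks covering n_bins, each at least
# 20 bins. Returns per-bin TAD index (1-based) and boundary bin indices
# (first bin of TADs 2..n).
tad_layout <- function(n_bins, n_tads, min_size = 20L) {
  stopifnot(n_tads * min_size <= n_bins)
  w <- as.vector(rmultinom(1, n_bins - n_tads * min_size, rep(1, n_tads))) + min_size
  bounds <- cumsum(w)
  tad_of <- rep(seq_len(n_tads), w)
  list(tad_of = tad_of, boundaries = head(bounds, -1L))
}

#' Simulate a contact matrix with planted TADs and distance decay
#'
#' Counts follow `base * d^(-decay_exponent) * (1 + tad_boost * same_block) *
#' exp(eps)` with `eps ~ N(0, noise_sd)` (log-normal multiplicative noise
#' keeps counts positive), for bin distances `d` in 1..200. When
#' `segment_effect_sd > 0` an additional per-1Mb-segment log-scale factor is
#' applied (half from each anchor's segment).
#'
#' @param spec A [synthetic_spec()].
#' @param chrom Chromosome name for the output.
#' @return A list: `contacts` (tibble chrom/bin1/bin2/count), `boundaries`
#'   (bin indices of planted block starts), `tad_of` (per-bin block index),
#'   `segment_log_effect` (per-segment factor, log scale).
#' @export
synth_contact_matrix <- function(spec, chrom = "chr1") {
  if (spec$decay_exponent <= 0) abort("decay_exponent must be positive")
  if (spec$n_bins < 2L * .MAX_BINS) abort("n_bins must be at least 400")
  n_seg <- ceiling(spec$n_bins * .RES / .SEGMENT_BP)
  seg_eff <- if (spec$segment_effect_sd > 0 && n_seg > 1) {
    spec$segment_effect_sd * seq(-1.5, 1.5, length.out = n_seg)
  } else {
    numeric(n_seg)
  }
  set.seed(spec$seed)
  layout <- tad_layout(spec$n_bins, spec$n_tads)
  pairs <- all_candidate_pairs(spec$n_bins)
  d <- pairs$bin2 - pairs$bin1
  same <- layout$tad_of[pairs$bin1 + 1L] == layout$tad_of[pairs$bin2 + 1L]
  seg1 <- bin_of(pairs$bin1 * .RES, .SEGMENT_BP) + 1L
  seg2 <- bin_of(pairs$bin2 * .RES, .SEGMENT_BP) + 1L
  mu <- spec$base * d^(-spec$decay_exponent) * (1 + spec$tad_boost * same) *
    exp((seg_eff[seg1] + seg_eff[seg2]) / 2)
  eps <- if (spec$noise_sd > 0) rnorm(length(mu), 0, spec$noise_sd) else 0
  contacts <- tibble(chrom = chrom, bin1 = pairs$bin1, bin2 = pairs$bin2,
                     count = mu * exp(eps))
  list(contacts = contacts, boundaries = layout$boundaries,
       tad_of = layout$tad_of, segment_log_effect = seg_eff)
}

#' All candidate bin pairs of a chromosome
#'
#' Every intra-chromosomal bin pair at 1..`max_bins` bin separation; the
#' candidate universe used by the loop caller, the evaluation metrics and
#' the feature builder.
#'
#' @param n_bins Number of 5 kb bins on the chromosome.
#' @param max_bins Maximum pair separation in bins (default 200 = 1 Mb).
#' @return Tibble (`bin1`, `bin2`) with `bin1 < bin2`.
#' @export
all_candidate_pairs <- function(n_bins, max_bins = .MAX_BINS) {
  max_d <- min(max_bins, n_bins - 1L)
  d <- unlist(lapply(seq_len(max_d), function(k) rep(k, n_bins - k)))
  i <- unlist(lapply(seq_len(max_d), function(k) seq_len(n_bins - k) - 1L))
  tibble(bin1 = as.integer(i), bin2 = as.integer(i + d))
}

#' Simulate the 10-track signal panel matched to a contact matrix
#'
#' Emulates the feature datasets of the regression stage: 7 continuous
#' ChIP/DNase-like tracks and 3 motif-count tracks. Two tracks carry the
#' structure the counts were generated from — `DNase1` takes a distinct
#' constant value per planted TAD (so anchor-level equality encodes
#' same-block) and the `CTCF` motif track peaks at planted boundaries — while
#' the remaining tracks are smooth or random nuisance signal. The generating
#' function mapping features back to noise-free counts is returned.
#'
#' @param spec A [synthetic_spec()].
#' @param cm Output of [synth_contact_matrix()] for the same spec.
#' @param chrom Chromosome name.
#' @return A list: `chip` (named list of 7 signal tibbles), `motif` (named
#'   list of 3 count tibbles), `generator` (function(anchor1_dnase,
#'   anchor2_dnase, distance_bins, segment_log) -> expected count).
#' @export
synth_signal_panel <- function(spec, cm, chrom = "chr1") {
  set.seed(spec$seed + 1L)
  n <- spec$n_bins
  tad_of <- cm$tad_of
  pos <- seq_len(n) - 1L

  # one distinct accessibility level per block, in a per-cell-type random
  # order: anchor-level equality encodes "same block" in every cell type,
  # but the value itself carries no positional information
  dnase <- as.numeric(sample(length(unique(tad_of)))[tad_of])
  # peaks flank each boundary (last bin of the old block and first bin of
  # the new one), as architectural-protein clusters do, so any pair window
  # that crosses a boundary contains at least one peak
  boundary_peak <- numeric(n)
  boundary_peak[cm$boundaries + 1L] <- 1
  boundary_peak[cm$boundaries] <- 1

  # nuisance tracks are iid per bin and drawn per cell type: spatially
  # unstructured signal cannot stand in for genomic position, so a model
  # trained in one cell type cannot memorize that cell type's block layout
  # through them
  tadnoise <- (tad_of %% 2) + runif(n, 0, 0.2)

  chip <- list(
    DNase1   = dnase,
    H3K4me3  = exp(rnorm(n, 0, 0.5)),
    H3K27ac  = exp(rnorm(n, 0, 0.5)),
    H3K4me1  = runif(n, 0.1, 2),
    H3K27me3 = rep(1, n) + runif(n, 0, 0.01),
    H3K36me3 = tadnoise,
    H3K9me3  = 1 + runif(n, 0, 0.5)
  )
  chip <- imap(chip, function(v, nm) {
    out <- signal_from_vector(v, chrom)
    attr(out, "label") <- nm
    out
  })

  # boundary CTCF clusters are strong relative to scattered background hits,
  # so the window motif rate separates within- from cross-block pairs at
  # every distance up to 1 Mb
  motif <- list(
    CTCF  = rpois(n, 0.05) + 25L * as.integer(boundary_peak > 0),
    RAD21 = rpois(n, 0.3),
    TBP   = rpois(n, 0.15)
  )
  motif <- imap(motif, function(v, nm) {
    out <- signal_from_vector(v, chrom)
    attr(out, "label") <- nm
    out
  })

  base <- spec$base; alpha <- spec$decay_exponent; boost <- spec$tad_boost
  generator <- function(anchor1_dnase, anchor2_dnase, distance_bins,
                        segment_log = 0) {
    same <- abs(anchor1_dnase - anchor2_dnase) < 0.5
    base * distance_bins^(-alpha) * (1 + boost * same) * exp(segment_log)
  }
  list(chip = chip, motif = motif, generator = generator)
}

#' Simulate multi-cell-type gene networks with planted modules
#'
#' Draws one stochastic-block-model graph per cell type over a shared gene
#' universe. All cell types share the planted module partition except for the
#' transitioning modules, whose genes are reassigned (as a block) to a
#' different module in a designated subtree of the cell-type tree.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `graphs` (named list of edge tibbles from/to/score),
#'   `tree` (ape phylo over cell types), `labels` (gene x cell-type matrix of
#'   planted module labels), `transitioning_genes` (character vector),
#'   `transition_cell_types` (leaves of the designated subtree), `genes`.
#' @export
synth_multi_celltype_networks <- function(spec) {
  if (spec$n_cell_types < 2L) abort("need at least 2 cell types")
  if (spec$n_modules * 2L > spec$n_genes) abort("module sizes exceed node count")
  set.seed(spec$seed + 2L)
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  cts <- sprintf("CT%d", seq_len(spec$n_cell_types))
  base_labels <- rep(seq_len(spec$n_modules), length.out = spec$n_genes) |>
    sort()

  # Two-clade ultrametric tree built by UPGMA on synthetic distances;
  # transitions happen in the second (smaller) clade.
  n1 <- ceiling(spec$n_cell_types / 2)
  clade_of <- rep(1:2, c(n1, spec$n_cell_types - n1))
  Dm <- outer(seq_len(spec$n_cell_types), seq_len(spec$n_cell_types),
              function(a, b) abs(a - b) * 0.2 + 1) +
    9 * outer(clade_of, clade_of, "!=")
  diag(Dm) <- 0
  dimnames(Dm) <- list(cts, cts)
  tree <- if (spec$n_cell_types == 2) {
    ape::read.tree(text = paste0("(", cts[1], ":1,", cts[2], ":1);"))
  } else {
    ape::as.phylo(hclust(as.dist(Dm), method = "average"))
  }
  transition_cts <- if (any(clade_of == 2)) cts[clade_of == 2] else
    cts[spec$n_cell_types]

  # half of each transitioning module moves (as a block) into another
  # module in the designated subtree; the other half stays, so every module
  # remains non-empty in every cell type
  trans_modules <- seq_len(spec$n_transitioning)
  trans_genes <- character(0)
  labels <- matrix(base_labels, nrow = spec$n_genes, ncol = spec$n_cell_types,
                   dimnames = list(genes, cts))
  for (m in trans_modules) {
    members <- which(base_labels == m)
    movers <- members[seq_len(length(members) %/% 2)]
    trans_genes <- c(trans_genes, genes[movers])
    target <- (m %% spec$n_modules) + 1L
    for (ct in transition_cts) labels[movers, ct] <- target
  }

  graphs <- lapply(cts, function(ct) {
    lab <- labels[, ct]
    idx <- which(upper.tri(matrix(0, spec$n_genes, spec$n_genes)), arr.ind = TRUE)
    p <- ifelse(lab[idx[, 1]] == lab[idx[, 2]], spec$p_within, spec$p_between)
    keep <- runif(nrow(idx)) < p
    tibble(from = genes[idx[keep, 1]], to = genes[idx[keep, 2]], score = 1)
  })
  names(graphs) <- cts
  list(graphs = graphs, tree = tree, labels = labels,
       transitioning_genes = trans_genes,
       transition_cell_types = transition_cts, genes = genes)
}

#' Simulate a SNP study around a set of called loops
#'
#' Places a chosen fraction of SNPs inside loop anchors whose partner anchor
#' overlaps a TSS window, so they acquire gene links downstream; the rest are
#' placed in bins with no such loop. A chosen subfraction of the planted
#' SNP-gene links is emitted as eQTL pairs.
#'
#' @param spec A [synthetic_spec()].
#' @param loops Significant-interaction tibble (chrom/bin1/bin2/count/p/q).
#' @param n_snps Number of lead SNPs to place. Default 40.
#' @param tss Optional TSS tibble (chrom/start/end/name); generated over loop
#'   anchors when NULL.
#' @return A list: `snps` (interval tibble, name = SNP id), `tss`, `ld`
#'   (tibble lead/proxy), `eqtl` (tibble snp_id/gene_id), `truth` (tibble of
#'   planted snp_id/gene_id links).
#' @export
synth_snp_study <- function(spec, loops, n_snps = 40L, tss = NULL) {
  if (nrow(loops) == 0) abort("loops must be non-empty")
  set.seed(spec$seed + 3L)
  chrom <- loops$chrom[[1]]
  if (is.null(tss)) {
    # one gene TSS at the midpoint of each distinct bin2 anchor
    gene_bins <- sort(unique(loops$bin2))
    tss <- tibble(chrom = chrom,
                  start = gene_bins * .RES + .RES %/% 2L,
                  end = gene_bins * .RES + .RES %/% 2L + 1L,
                  name = sprintf("gene%03d", seq_along(gene_bins)),
                  score = NA_real_)
  }
  tss_bins <- bin_of(tss$start)
  linked_loops <- loops |> filter(.data$bin2 %in% tss_bins)
  if (nrow(linked_loops) == 0) abort("no loop anchor pairs with a TSS partner")
  n_linked <- round(spec$snp_linked_frac * n_snps)

  pick <- linked_loops[sample.int(nrow(linked_loops), n_linked, replace = TRUE), ]
  linked_pos <- pick$bin1 * .RES + sample.int(.RES, n_linked, replace = TRUE) - 1L
  loop_bins <- unique(c(loops$bin1, loops$bin2))
  free_bins <- setdiff(seq_len(max(loops$bin2) + 1L) - 1L, c(loop_bins, tss_bins))
  unlinked_pos <- sample(free_bins, n_snps - n_linked, replace = TRUE) * .RES +
    sample.int(.RES, n_snps - n_linked, replace = TRUE) - 1L
  pos <- c(linked_pos, unlinked_pos)
  snps <- tibble(chrom = chrom, start = pos, end = pos + 1L,
                 name = sprintf("rs%04d", seq_len(n_snps)), score = NA_real_)

  # planted SNP-gene links: every loop from a planted SNP's bin whose
  # partner anchor carries a TSS (SNPs can pick up links beyond the loop
  # they were seeded into)
  oriented <- bind_rows(tibble(snp_bin = loops$bin1, gene_bin = loops$bin2),
                        tibble(snp_bin = loops$bin2, gene_bin = loops$bin1))
  truth <- tibble(snp_id = snps$name, snp_bin = bin_of(snps$start)) |>
    inner_join(oriented, by = "snp_bin", relationship = "many-to-many") |>
    inner_join(tibble(gene_bin = tss_bins, gene_id = tss$name), by = "gene_bin",
               relationship = "many-to-many") |>
    distinct(.data$snp_id, .data$gene_id, .keep_all = TRUE)

  ld <- tibble(lead = snps$name[1], proxy = snps$name[1])[0, ]
  n_eqtl <- round(spec$eqtl_frac * nrow(truth))
  eqtl <- truth[sample.int(nrow(truth), n_eqtl), c("snp_id", "gene_id")]
  list(snps = snps, tss = tss, ld = ld, eqtl = eqtl, truth = truth)
}
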