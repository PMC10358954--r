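# Assembly of cell-type-specific gene networks (PPI + proximal TF-gene +
# loop-mediated distal TF-gene edges) and inference of the cell-type
# relationship tree by UPGMA.

top_fraction <- function(edges, top_frac) {
  if (nrow(edges) == 0) return(edges)
  n_keep <- ceiling(top_frac * nrow(edges))
  cutoff <- sort(edges$score, decreasing = TRUE)[n_keep]
  filter(edges, .data$score >= cutoff)  # ties at the cutoff all retained
}

#' Proximal TF-to-gene network from accessible motifs in promoters
#'
#' A TF-gene edge is a candidate when a motif hit with purity score strictly
#' above `purity_min` lies inside the gene's TSS window `[tss - 2500,
#' tss + 2500)`. Candidates are ranked by their best hit purity and the top
#' `top_frac` are retained (ties at the cutoff included).
#'
#' @param motif_hits Interval tibble of motif hits; `name` = TF, `score` =
#'   purity.
#' @param tss Interval tibble of TSSs (`name` = gene id).
#' @param purity_min Strict purity threshold (default 0.9).
#' @param top_frac Fraction of candidate edges kept (default 0.05).
#' @return Edge tibble (`from` = TF, `to` = gene, `score` = best purity,
#'   `provenance` = "proximal").
#' @export
build_proximal_network <- function(motif_hits, tss, purity_min = 0.9,
                                   top_frac = 0.05) {
  hits <- filter(motif_hits, .data$score > purity_min)
  if (nrow(hits) == 0 || nrow(tss) == 0) {
    return(tibble(from = character(), to = character(), score = numeric(),
                  provenance = character()))
  }
  cand <- map(seq_len(nrow(tss)), function(r) {
    lo <- tss$start[r] - 2500L
    hi <- tss$start[r] + 2500L
    inwin <- hits$chrom == tss$chrom[r] & hits$start >= lo & hits$start < hi
    if (!any(inwin)) return(NULL)
    tibble(from = hits$name[inwin], to = tss$name[r],
           score = hits$score[inwin])
  }) |>
    list_rbind() |>
    group_by(.data$from, .data$to) |>
    summarise(score = max(.data$score), .groups = "drop")
  top_fraction(cand, top_frac) |>
    mutate(provenance = "proximal") |>
    arrange(desc(.data$score), .data$from, .data$to)
}

#' Distal TF-to-gene network mediated by significant interactions
#'
#' For each significant loop with one anchor overlapping a gene's TSS window,
#' qualifying motif hits (purity strictly > `purity_min`) in the *other*
#' anchor create TF-gene candidate edges; hits falling in the TSS anchor
#' itself are proximal territory and excluded. The same best-purity ranking
#' and top-fraction filter as the proximal network applies, separately
#' within the distal class.
#'
#' @inheritParams build_proximal_network
#' @param loops Significant-interaction tibble.
#' @return Edge tibble with `provenance` = "distal" and the supporting loop
#'   anchors (`snp_side_bin`, `tss_side_bin`).
#' @export
build_distal_network <- function(motif_hits, tss, loops, purity_min = 0.9,
                                 top_frac = 0.05) {
  empty <- tibble(from = character(), to = character(), score = numeric(),
                  provenance = character(), motif_bin = integer(),
                  tss_bin = integer())
  hits <- filter(motif_hits, .data$score > purity_min)
  if (nrow(hits) == 0 || nrow(loops) == 0 || nrow(tss) == 0) return(empty)
  gene_bins <- tss_window_bins(tss) |> rename(tss_bin = "bin")
  hit_bins <- tibble(from = hits$name, motif_bin = bin_of(hits$start),
                     score = hits$score)
  oriented <- bind_rows(
    tibble(tss_bin = loops$bin1, motif_bin_loop = loops$bin2),
    tibble(tss_bin = loops$bin2, motif_bin_loop = loops$bin1))
  cand <- gene_bins |>
    inner_join(oriented, by = "tss_bin", relationship = "many-to-many") |>
    inner_join(hit_bins, by = c(motif_bin_loop = "motif_bin"),
               relationship = "many-to-many") |>
    filter(.data$motif_bin_loop != .data$tss_bin) |>
    rename(to = "gene_id", motif_bin = "motif_bin_loop") |>
    group_by(.data$from, .data$to) |>
    slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup()
  top_fraction(cand, top_frac) |>
    mutate(provenance = "distal") |>
    select("from", "to", "score", "provenance", "motif_bin", "tss_bin") |>
    arrange(desc(.data$score), .data$from, .data$to)
}

#' Merge PPI, proximal and distal edges into one cell-type graph
#'
#' The merged graph is undirected and unweighted (weight 1 per retained
#' edge); duplicate edges keep the union of their provenances; self-loops
#' are dropped.
#'
#' @param ppi Edge tibble (`from`, `to`) of protein-protein interactions.
#' @param proximal,distal Edge tibbles from the builders above.
#' @return An object of class `cell_type_graph`: list with `nodes` and
#'   `edges` (`from`, `to`, `provenance`).
#' @export
merge_networks <- function(ppi = NULL, proximal = NULL, distal = NULL) {
  tag <- function(df, prov) {
    if (is.null(df) || nrow(df) == 0) {
      return(tibble(from = character(), to = character(),
                    provenance = character()))
    }
    tibble(from = pmin(df$from, df$to), to = pmax(df$from, df$to),
           provenance = prov)
  }
  edges <- bind_rows(tag(ppi, "ppi"), tag(proximal, "proximal"),
                     tag(distal, "distal")) |>
    filter(.data$from != .data$to) |>
    group_by(.data$from, .data$to) |>
    summarise(provenance = paste(sort(unique(.data$provenance)),
                                 collapse = ","), .groups = "drop") |>
    arrange(.data$from, .data$to)
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "cell_type_graph")
}

#' @export
print.cell_type_graph <- function(x, ...) {
  cat(sprintf("<cell_type_graph> %d nodes, %d edges (%s)\n", length(x$nodes),
              nrow(x$edges),
              paste(names(table(x$edges$provenance)), collapse = "; ")))
  invisible(x)
}

#' Dense symmetric 0/1 adjacency matrix of a graph
#'
#' @param graph A `cell_type_graph`, an edge tibble, or an adjacency matrix
#'   (returned unchanged).
#' @param nodes Optional node universe (defaults to the nodes present).
#' @return Symmetric numeric matrix with dimnames.
#' @export
graph_adjacency <- function(graph, nodes = NULL) {
  if (is.matrix(graph)) return(graph)
  edges <- if (inherits(graph, "cell_type_graph")) graph$edges else graph
  nodes <- nodes %||% if (inherits(graph, "cell_type_graph")) graph$nodes else
    sort(unique(c(edges$from, edges$to)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  keep <- edges$from %in% nodes & edges$to %in% nodes
  i <- match(edges$from[keep], nodes)
  j <- match(edges$to[keep], nodes)
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  diag(A) <- 0
  A
}

#' Infer the cell-type tree from promoter signal
#'
#' UPGMA (average-linkage hierarchical clustering) on the Euclidean
#' distances between the cell types' promoter-bin signal profiles
#' (e.g. H3K4me3).
#'
#' @param signal_matrix Numeric matrix, cell types x promoter bins, with
#'   unique rownames.
#' @return An `ape` phylo tree (ultrametric).
#' @export
infer_tree_signal <- function(signal_matrix) {
  if (nrow(signal_matrix) < 2) abort("need at least 2 cell types")
  if (anyDuplicated(rownames(signal_matrix))) {
    abort("duplicate cell-type names")
  }
  hc <- hclust(dist(signal_matrix, method = "euclidean"), method = "average")
  ape::as.phylo(hc)
}

#' Infer the cell-type tree from shared significant interactions
#'
#' Pairwise F-scores (2PR/(P+R) of shared loop pairs) between cell types are
#' assembled into per-cell-type F-score profiles, converted to a Euclidean
#' distance matrix and clustered with UPGMA.
#'
#' @param loop_sets Named list of significant-interaction tibbles.
#' @return A list: `tree` (phylo) and `fscore` (symmetric matrix).
#' @export
interaction_fscore_tree <- function(loop_sets) {
  if (length(loop_sets) < 2) abort("need at least 2 loop sets")
  cts <- names(loop_sets)
  keys <- map(loop_sets, function(df) {
    unique(paste(df$chrom, df$bin1, df$bin2))
  })
  n <- length(cts)
  FM <- matrix(1, n, n, dimnames = list(cts, cts))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      inter <- length(intersect(keys[[a]], keys[[b]]))
      P <- if (length(keys[[a]]) > 0) inter / length(keys[[a]]) else 0
      R <- if (length(keys[[b]]) > 0) inter / length(keys[[b]]) else 0
      f <- if (P + R > 0) 2 * P * R / (P + R) else 0
      FM[a, b] <- FM[b, a] <- f
    }
  }
  hc <- hclust(dist(FM, method = "euclidean"), method = "average")
  list(tree = ape::as.phylo(hc), fscore = FM)
}

#' Fowlkes-Mallows comparison of two trees at k clusters
#'
#' Both trees are cut into k clusters; `B_k = TP / sqrt((TP+FP)(TP+FN))`
#' over leaf pairs, with a permutation null obtained by shuffling the leaf
#' labels of one tree.
#'
#' @param tree1,tree2 Ultrametric phylo trees (or hclust objects) over the
#'   same leaves.
#' @param k Number of clusters, in `[2, n - 1]`.
#' @param n_perm Permutations for the null (default 1000).
#' @param seed Seed for the permutation null.
#' @return Tibble with `k`, `index`, `null_mean`, `null_sd`, `perm_p`.
#' @export
fowlkes_mallows <- function(tree1, tree2, k, n_perm = 1000L, seed = 1L) {
  as_hc <- function(tr) if (inherits(tr, "hclust")) tr else ape::as.hclust.phylo(tr)
  h1 <- as_hc(tree1); h2 <- as_hc(tree2)
  n <- length(h1$labels)
  if (k < 2 || k > n - 1) abort("k must lie in [2, n-1]")
  c1 <- cutree(h1, k = k)
  c2 <- cutree(h2, k = k)[names(c1)]
  bk <- function(a, b) {
    ct <- table(a, b)
    TPfp <- sum(choose(rowSums(ct), 2))
    TPfn <- sum(choose(colSums(ct), 2))
    TP <- sum(choose(ct, 2))
    if (TPfp == 0 || TPfn == 0) return(0)
    TP / sqrt(TPfp * TPfn)
  }
  idx <- bk(c1, c2)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) bk(c1, sample(c2)), numeric(1))
  tibble(k = k, index = idx, null_mean = mean(null), null_sd = sd(null),
         perm_p = (sum(null >= idx) + 1) / (n_perm + 1))
}
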