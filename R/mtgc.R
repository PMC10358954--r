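# Tree-guided multi-task spectral clustering. Each cell type's similarity
# matrix is embedded with the k smallest eigenvectors of the regularized
# graph Laplacian L_tau = I - D_tau^{-1/2} A D_tau^{-1/2} (D_tau = D +
# mean(D)); embeddings are aligned to a leaf-averaged reference by
# orthogonal Procrustes and clustered root-to-leaf along the cell-type
# tree, each node's k-means warm-started from its parent's centroids, which
# makes cluster label c mean the same thing in every cell type.

#' Spectral embedding of a similarity matrix
#'
#' Zeroes the diagonal, forms the regularized Laplacian
#' `L_tau = I - D_tau^{-1/2} A D_tau^{-1/2}` with `D_tau = D + mean(D)`, and
#' returns the eigenvectors of the k smallest eigenvalues with rows
#' normalized to unit length (all-zero rows stay zero).
#'
#' @param S Symmetric non-negative similarity matrix with dimnames.
#' @param k Embedding dimension / cluster count.
#' @return n x k matrix of embedded coordinates (rownames kept).
#' @export
spectral_embed <- function(S, k) {
  n <- nrow(S)
  if (k >= n) abort("k must be smaller than the number of nodes")
  if (any(S < 0)) abort("similarity matrix must be non-negative")
  A <- S
  diag(A) <- 0
  d <- rowSums(A)
  d_tau <- d + mean(d)
  if (any(d_tau <= 0)) abort("regularized degrees must be positive")
  dinv <- 1 / sqrt(d_tau)
  L <- -(dinv %o% dinv) * A
  diag(L) <- diag(L) + 1
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- eig$vectors[, n:(n - k + 1), drop = FALSE]  # increasing eigenvalue
  nrm <- sqrt(rowSums(U^2))
  U <- U / ifelse(nrm > 0, nrm, 1)
  rownames(U) <- rownames(S)
  U
}

# Orthogonal Procrustes rotation of X onto ref (both n x k).
procrustes_align <- function(X, ref) {
  s <- svd(crossprod(X, ref))
  X %*% (s$u %*% t(s$v))
}

# k-means++ seeding (Arthur & Vassilvitskii) on rows of x.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (c in seq_len(k)[-1]) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[c, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[c, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

# Lloyd iterations from given centers; empty clusters keep their previous
# centroid so the cluster-index correspondence never collapses.
warm_kmeans <- function(x, centers, iter_max = 100L) {
  k <- nrow(centers)
  labels <- integer(nrow(x))
  for (it in seq_len(iter_max)) {
    d2 <- vapply(seq_len(k), function(c) {
      rowSums((x - matrix(centers[c, ], nrow(x), ncol(x), byrow = TRUE))^2)
    }, numeric(nrow(x)))
    new_labels <- max.col(-d2, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (c in seq_len(k)) {
      if (any(labels == c)) {
        centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
      }
    }
  }
  wss <- sum(vapply(seq_len(k), function(c) {
    if (!any(labels == c)) return(0)
    sum(sweep(x[labels == c, , drop = FALSE], 2, centers[c, ])^2)
  }, numeric(1)))
  list(labels = labels, centers = centers, wss = wss)
}

phylo_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

phylo_leaf_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  unlist(lapply(phylo_children(tree, node), phylo_leaf_tips, tree = tree))
}

#' Tree-guided multi-task clustering of per-cell-type similarities
#'
#' @param S_list Named list (by cell type) of similarity matrices over the
#'   same gene universe (identical rownames).
#' @param tree Phylo tree whose tips are the cell types.
#' @param k Number of clusters (default 7).
#' @param seed Integer seed (root k-means++ restarts).
#' @param n_start Restarts of the root k-means (default 50).
#' @return Object of class `mtgc_fit`: `labels` (gene x cell-type integer
#'   matrix, cluster identities matched across cell types), `embeddings`,
#'   `k`, `tree`.
#' @export
multitask_cluster <- function(S_list, tree, k = 7L, seed = 1L,
                              n_start = 50L) {
  cts <- names(S_list)
  if (!setequal(tree$tip.label, cts)) {
    abort("tree leaves must match the cell types of S_list")
  }
  genes <- rownames(S_list[[1]])
  for (S in S_list) {
    if (!identical(rownames(S), genes)) {
      abort("all similarity matrices must share one gene universe")
    }
  }
  ref_S <- Reduce(`+`, S_list) / length(S_list)
  ref_emb <- spectral_embed(ref_S, k)
  embeddings <- map(S_list, function(S) {
    procrustes_align(spectral_embed(S, k), ref_emb)
  })

  set.seed(seed)
  root_fit <- NULL
  for (i in seq_len(n_start)) {
    fit <- warm_kmeans(ref_emb, kmeanspp_centers(ref_emb, k))
    if (is.null(root_fit) || fit$wss < root_fit$wss) root_fit <- fit
  }

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  centers_at <- list()
  centers_at[[as.character(root)]] <- root_fit$centers
  labels <- matrix(NA_integer_, length(genes), length(cts),
                   dimnames = list(genes, cts))
  # breadth-first: every node's k-means is warm-started from its parent
  queue <- root
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    for (child in phylo_children(tree, node)) {
      tips <- phylo_leaf_tips(tree, child)
      node_emb <- Reduce(`+`, embeddings[tree$tip.label[tips]]) / length(tips)
      fit <- warm_kmeans(node_emb, centers_at[[as.character(node)]])
      centers_at[[as.character(child)]] <- fit$centers
      if (child <= n_tip) {
        labels[, tree$tip.label[child]] <- fit$labels
      } else {
        queue <- c(queue, child)
      }
    }
  }
  structure(list(labels = labels, embeddings = embeddings, k = k,
                 tree = tree, seed = seed),
            class = "mtgc_fit")
}

#' @export
tidy.mtgc_fit <- function(x, ...) {
  as_tibble(x$labels, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_type",
                        values_to = "cluster")
}

#' @export
glance.mtgc_fit <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$labels), n_cell_types = ncol(x$labels),
         seed = x$seed)
}

#' @export
print.mtgc_fit <- function(x, ...) {
  cat(sprintf("<mtgc_fit> %d genes x %d cell types, k = %d\n", nrow(x$labels),
              ncol(x$labels), x$k))
  invisible(x)
}

#' @export
autoplot.mtgc_fit <- function(object, ...) {
  df <- tidy(object)
  ord <- order(object$labels[, 1])
  df$gene_id <- factor(df$gene_id, levels = rownames(object$labels)[ord])
  ggplot(df, aes(x = .data$cell_type, y = .data$gene_id,
                 fill = factor(.data$cluster))) +
    geom_tile() +
    labs(x = NULL, y = "genes", fill = "cluster") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Newman modularity of a partition on a weighted graph
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` with e_c the within-cluster edge
#' weight, d_c the total degree of cluster c and m the total edge weight.
#'
#' @param W Symmetric weighted adjacency (diagonal ignored).
#' @param labels Integer cluster labels aligned to rows of W.
#' @return Modularity value.
#' @export
modularity_score <- function(W, labels) {
  diag(W) <- 0
  m2 <- sum(W)  # = 2m
  if (m2 == 0) return(0)
  d <- rowSums(W)
  sum(vapply(unique(labels), function(c) {
    idx <- labels == c
    sum(W[idx, idx]) / m2 - (sum(d[idx]) / m2)^2
  }, numeric(1)))
}

#' Select the cluster count by modularity and minimum cluster size
#'
#' Runs [multitask_cluster()] for each k in the grid, scores each k by the
#' average (over cell types) Newman modularity of the partition on the
#' similarity-weighted graphs, and picks the k with the best modularity
#' among those whose smallest cluster has at least `min_size` genes (falling
#' back to the unconstrained best if none qualifies).
#'
#' @inheritParams multitask_cluster
#' @param grid Candidate k values (default 6:9).
#' @param min_size Minimum admissible cluster size (default 5).
#' @return A list: `k` (selected) and `table` (per-k modularity and minimum
#'   cluster size).
#' @export
select_k <- function(S_list, tree, grid = 6:9, min_size = 5L, seed = 1L) {
  tab <- map(grid, function(k) {
    fit <- multitask_cluster(S_list, tree, k = k, seed = seed)
    mods <- map_dbl(names(S_list), function(ct) {
      modularity_score(S_list[[ct]], fit$labels[, ct])
    })
    sizes <- apply(fit$labels, 2, function(l) min(table(factor(l, levels = seq_len(k)))))
    tibble(k = k, modularity = mean(mods), min_cluster_size = min(sizes))
  }) |>
    list_rbind()
  ok <- tab |> filter(.data$min_cluster_size >= min_size)
  pick <- if (nrow(ok) > 0) ok else tab
  list(k = pick$k[which.max(pick$modularity)], table = tab)
}

#' Detect conserved and transitioning gene sets from cluster assignments
#'
#' Genes are clustered by the Hamming fraction between their cluster-label
#' vectors (share of cell types where the labels disagree) with
#' average-linkage hierarchical clustering cut at `cut_height`; sets smaller
#' than `min_genes` are dropped. A set is conserved when every member keeps
#' one single label in every cell type, transitioning otherwise.
#'
#' @param labels Gene x cell-type label matrix (from an `mtgc_fit`).
#' @param direct_hits Optional named list (by cell type) of direct-hit gene
#'   ids used to flag SNP-associated sets.
#' @param cut_height Tree cut height on the Hamming-fraction scale
#'   (default 0.1).
#' @param min_genes Minimum set size (default 5).
#' @return Tibble: `set_id`, `genes` (list-column), `n_genes`, `status`
#'   ("conserved"/"transitioning"), `snp_associated`, `majority_labels`
#'   (list-column of per-cell-type majority labels).
#' @export
transitioning_gene_sets <- function(labels, direct_hits = NULL,
                                    cut_height = 0.1, min_genes = 5L) {
  n <- nrow(labels)
  D <- matrix(0, n, n)
  for (ct in seq_len(ncol(labels))) {
    D <- D + outer(labels[, ct], labels[, ct], "!=")
  }
  D <- D / ncol(labels)
  hc <- hclust(as.dist(D), method = "average")
  sets <- cutree(hc, h = cut_height)
  hit_genes <- unique(unlist(direct_hits))
  out <- map(unique(sets), function(s) {
    members <- rownames(labels)[sets == s]
    if (length(members) < min_genes) return(NULL)
    sub <- labels[members, , drop = FALSE]
    maj <- apply(sub, 2, function(col) {
      as.integer(names(sort(table(col), decreasing = TRUE))[1])
    })
    tibble(set_id = s, genes = list(members), n_genes = length(members),
           status = if (length(unique(as.vector(sub))) == 1L) "conserved"
                    else "transitioning",
           snp_associated = any(members %in% hit_genes),
           majority_labels = list(maj))
  }) |>
    list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(set_id = integer(), genes = list(), n_genes = integer(),
                  status = character(), snp_associated = logical(),
                  majority_labels = list()))
  }
  out |> mutate(set_id = dplyr::row_number())
}

#' Hypergeometric enrichment of a gene set against annotation terms
#'
#' Upper-tail hypergeometric p-value per term (conditioning every term on
#' the background), BH-corrected across terms; terms with no background
#' overlap are skipped.
#'
#' @param genes Character vector (the gene list; must lie in `background`).
#' @param annotation Tibble (`term`, `gene_id`).
#' @param background Character vector of background genes.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return Tibble: `term`, `overlap`, `term_size`, `p`, `q`, `significant`.
#' @export
hypergeom_enrichment <- function(genes, annotation, background,
                                 alpha = 0.05) {
  if (!all(genes %in% background)) abort("gene set must lie within the background")
  N <- length(unique(background))
  n <- length(unique(genes))
  res <- annotation |>
    filter(.data$gene_id %in% background) |>
    group_by(.data$term) |>
    summarise(term_size = dplyr::n_distinct(.data$gene_id),
              overlap = sum(unique(.data$gene_id) %in% genes),
              .groups = "drop") |>
    filter(.data$term_size > 0) |>
    mutate(p = phyper(.data$overlap - 1, .data$term_size, N - .data$term_size,
                      n, lower.tail = FALSE))
  res |>
    mutate(q = bh_qvalues(.data$p), significant = .data$q < alpha) |>
    arrange(.data$p)
}

#' Summarize an enrichment matrix with non-negative matrix factorization
#'
#' Rank-k NMF by multiplicative updates (Frobenius objective, seeded random
#' initialization, fixed iteration cap), reporting the explained variance
#' `EV = 1 - var(x - xhat) / var(x)` and, per factor, the top terms (rows)
#' and top columns by factor loading.
#'
#' @param X Non-negative matrix, terms x gene lists, with dimnames.
#' @param k Factorization rank (default 7).
#' @param seed Integer seed.
#' @param max_iter Iteration cap (default 2000).
#' @param n_top_terms,n_top_cols Sizes of the reported top lists.
#' @return Object of class `nmf_summary`: `W`, `H`, `ev`, `top_terms`,
#'   `top_columns`.
#' @export
nmf_summarize <- function(X, k = 7L, seed = 1L, max_iter = 2000L,
                          n_top_terms = 10L, n_top_cols = 5L) {
  if (any(X < 0)) abort("NMF input must be non-negative")
  set.seed(seed)
  eps <- 1e-9
  n <- nrow(X); m <- ncol(X)
  W <- matrix(runif(n * k, 0, max(X)), n, k)
  H <- matrix(runif(k * m, 0, 1), k, m)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  Xhat <- W %*% H
  ev <- 1 - var(as.vector(X - Xhat)) / var(as.vector(X))
  rn <- rownames(X) %||% as.character(seq_len(n))
  cn <- colnames(X) %||% as.character(seq_len(m))
  top_terms <- map(seq_len(k), function(f) {
    rn[order(W[, f], decreasing = TRUE)[seq_len(min(n_top_terms, n))]]
  })
  top_columns <- map(seq_len(k), function(f) {
    cn[order(H[f, ], decreasing = TRUE)[seq_len(min(n_top_cols, m))]]
  })
  structure(list(W = W, H = H, ev = ev, top_terms = top_terms,
                 top_columns = top_columns, k = k),
            class = "nmf_summary")
}

#' @export
print.nmf_summary <- function(x, ...) {
  cat(sprintf("<nmf_summary> rank %d, explained variance %.4f\n", x$k, x$ev))
  invisible(x)
}

#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the worst ratio `(s_i + s_j) / M_ij` between
#' within-cluster scatter and centroid separation; lower is better.
#'
#' @param X Point coordinates (rows) used for the clustering.
#' @param labels Integer cluster labels.
#' @return The index.
#' @export
davies_bouldin <- function(X, labels) {
  cls <- sort(unique(labels))
  if (length(cls) < 2) abort("need at least 2 clusters")
  cent <- t(vapply(cls, function(c) colMeans(X[labels == c, , drop = FALSE]),
                   numeric(ncol(X))))
  s <- vapply(seq_along(cls), function(ci) {
    pts <- X[labels == cls[ci], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[ci, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(cent))
  mean(vapply(seq_along(cls), function(i) {
    max(vapply(seq_along(cls)[-i], function(j) (s[i] + s[j]) / M[i, j],
               numeric(1)))
  }, numeric(1)))
}
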