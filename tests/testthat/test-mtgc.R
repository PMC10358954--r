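block_similarity <- function(sizes, within = 1, between = 0.02, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- matrix(between, n, n) + (within - between) * outer(lab, lab, "==")
  S <- S + matrix(runif(n * n, 0, 0.01), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  list(S = S, labels = lab)
}

test_that("spectral embedding separates blocks and solves the eigenproblem", {
  bs <- block_similarity(c(20, 20, 20))
  U <- spectral_embed(bs$S, k = 3)
  km <- kmeans(U, centers = 3, nstart = 10)
  expect_equal(mclust::adjustedRandIndex(km$cluster, bs$labels), 1)

  # residual oracle on the un-normalized eigenvectors
  A <- bs$S; diag(A) <- 0
  d <- rowSums(A); dt <- d + mean(d)
  L <- diag(nrow(A)) - diag(1 / sqrt(dt)) %*% A %*% diag(1 / sqrt(dt))
  eg <- eigen(L, symmetric = TRUE)
  n <- nrow(A)
  for (j in (n - 2):n) {
    expect_lt(max(abs(L %*% eg$vectors[, j] - eg$values[j] * eg$vectors[, j])),
              1e-8)
  }
  expect_error(spectral_embed(bs$S, k = 60), "smaller")

  # permuting node order permutes the embedded subspace identically
  set.seed(2)
  perm <- sample(nrow(bs$S))
  U2 <- spectral_embed(bs$S[perm, perm], k = 3)
  proj1 <- tcrossprod(U[perm, ] / sqrt(rowSums(U[perm, ]^2)))
  proj2 <- tcrossprod(U2 / sqrt(rowSums(U2^2)))
  expect_equal(proj1, proj2, tolerance = 1e-6)
})

test_that("multitask clustering matches cluster identities across cell types", {
  bs <- block_similarity(c(25, 25, 25))
  S_list <- list(CT1 = bs$S, CT2 = bs$S, CT3 = bs$S)
  tree <- ape::read.tree(text = "((CT1:1,CT2:1):1,CT3:2);")
  fit <- multitask_cluster(S_list, tree, k = 3, seed = 1)
  # identical inputs give identical label columns
  expect_equal(fit$labels[, "CT1"], fit$labels[, "CT2"])
  expect_equal(fit$labels[, "CT1"], fit$labels[, "CT3"])
  expect_equal(mclust::adjustedRandIndex(fit$labels[, 1], bs$labels), 1)

  # deterministic given the seed
  fit2 <- multitask_cluster(S_list, tree, k = 3, seed = 1)
  expect_identical(fit$labels, fit2$labels)

  bad_tree <- ape::read.tree(text = "((X:1,CT2:1):1,CT3:2);")
  expect_error(multitask_cluster(S_list, bad_tree, k = 3), "match")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$k, 3L)
})

test_that("planted multi-cell-type modules are recovered with matched labels", {
  spec <- synthetic_spec(n_genes = 300, n_modules = 6, n_cell_types = 3,
                         seed = 23)
  net <- synth_multi_celltype_networks(spec)
  S_list <- lapply(net$graphs, graph_adjacency, nodes = net$genes)
  fit <- multitask_cluster(S_list, net$tree, k = 6, seed = 1)
  for (ct in colnames(fit$labels)) {
    expect_gte(mclust::adjustedRandIndex(fit$labels[, ct], net$labels[, ct]),
               0.9)
  }
  # consistent relabeling leaves transitioning-set detection invariant
  tgs <- transitioning_gene_sets(fit$labels)
  relabeled <- apply(fit$labels, 2, function(l) c(3, 1, 2, 6, 5, 4)[l])
  rownames(relabeled) <- rownames(fit$labels)
  tgs2 <- transitioning_gene_sets(relabeled)
  expect_equal(tgs$n_genes, tgs2$n_genes)
  expect_equal(tgs$status, tgs2$status)
})

test_that("modularity matches the direct double-sum and igraph on small graphs", {
  # two disconnected equal cliques at k = 2: closed form 0.5
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1; A[6:10, 6:10] <- 1; diag(A) <- 0
  expect_equal(modularity_score(A, rep(1:2, each = 5)), 0.5)
  expect_equal(modularity_score(A, rep(1, 10)), 0)

  set.seed(11)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    W <- matrix(runif(n * n), n, n) * rbinom(n * n, 1, 0.2)
    W <- (W + t(W)) / 2; diag(W) <- 0
    lab <- sample(3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_score(W, lab),
                 igraph::modularity(g, lab, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
    # direct double-sum oracle
    m2 <- sum(W); d <- rowSums(W)
    q <- sum((W - outer(d, d) / m2)[outer(lab, lab, "==")]) / m2
    expect_equal(modularity_score(W, lab), q, tolerance = 1e-12)
  }
})

test_that("select_k prefers the planted cluster count", {
  spec <- synthetic_spec(n_genes = 240, n_modules = 6, n_cell_types = 3,
                         seed = 29)
  net <- synth_multi_celltype_networks(spec)
  S_list <- lapply(net$graphs, graph_adjacency, nodes = net$genes)
  sk <- select_k(S_list, net$tree, grid = 5:8, seed = 1)
  expect_equal(sk$k, 6L)
  expect_equal(nrow(sk$table), 4L)
})

test_that("transitioning-set detection separates conserved from switching genes", {
  labels <- rbind(
    matrix(1L, 10, 3), matrix(2L, 10, 3),
    cbind(rep(3L, 8), rep(3L, 8), rep(1L, 8)),   # switches in CT3
    matrix(4L, 4, 3))                            # below the size floor
  rownames(labels) <- sprintf("g%02d", seq_len(nrow(labels)))
  colnames(labels) <- paste0("CT", 1:3)
  tgs <- transitioning_gene_sets(labels,
                                 direct_hits = list(CT1 = "g01"))
  expect_equal(nrow(tgs), 3L)
  expect_setequal(tgs$status, c("conserved", "conserved", "transitioning"))
  tr <- tgs[tgs$status == "transitioning", ]
  expect_equal(tr$n_genes, 8L)
  expect_false(any(vapply(tgs$genes, function(g) "g29" %in% g, logical(1))))
  expect_true(tgs$snp_associated[vapply(tgs$genes, function(g) "g01" %in% g,
                                        logical(1))])
})

test_that("hypergeometric enrichment matches exact enumeration", {
  background <- sprintf("g%02d", 1:10)
  annotation <- tibble::tibble(term = "T1", gene_id = background[1:5])
  res <- hypergeom_enrichment(background[1:5], annotation, background)
  expect_equal(res$p, 1 / choose(10, 5))        # = 1/252
  expect_equal(res$p, 1 / 252, tolerance = 1e-12)

  # whole background as the set: p = 1 for every term
  res_all <- hypergeom_enrichment(background, annotation, background)
  expect_equal(res_all$p, 1)

  # overlap at its expectation is unremarkable
  annotation2 <- tibble::tibble(term = "T2", gene_id = background[1:4])
  res_mid <- hypergeom_enrichment(background[c(1, 2, 6, 7, 8)],
                                  annotation2, background)
  expect_gt(res_mid$p, 0.2)
  expect_error(hypergeom_enrichment("zzz", annotation, background), "within")
})

test_that("NMF reaches near-exact reconstruction in the low-rank regime", {
  set.seed(13)
  W0 <- matrix(runif(50 * 7), 50, 7)
  H0 <- matrix(runif(7 * 30), 7, 30)
  X <- W0 %*% H0
  rownames(X) <- sprintf("term%02d", 1:50)
  colnames(X) <- sprintf("list%02d", 1:30)
  nm <- nmf_summarize(X, k = 7, seed = 1)
  expect_gte(nm$ev, 0.999)
  Xhat <- nm$W %*% nm$H
  expect_true(all(Xhat >= 0))
  # EV formula equals the direct variance-ratio recomputation
  expect_equal(nm$ev, 1 - var(as.vector(X - Xhat)) / var(as.vector(X)))
  expect_equal(length(nm$top_terms), 7L)
  expect_equal(length(nm$top_columns[[1]]), 5L)
  expect_error(nmf_summarize(-X, k = 2), "non-negative")
})

test_that("Davies-Bouldin rewards separated clusters", {
  set.seed(15)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 8), ncol = 2))
  good <- rep(1:2, each = 30)
  expect_lt(davies_bouldin(X, good), davies_bouldin(X, sample(good)))
  expect_error(davies_bouldin(X, rep(1, 60)), "2 clusters")
})
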