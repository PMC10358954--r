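test_that("node diffusion solves the regularized Laplacian system", {
  A <- random_connected_adjacency(60, 0.1, seed = 1)
  Q <- setNames(numeric(60), rownames(A))
  Q[c(3, 10, 25)] <- c(2, 1, 4)
  V <- node_diffusion(A, Q, lambda = 1)

  # solve residual, directly assertable from the kernel definition
  d <- rowSums(A)
  L <- diag(60) - diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  expect_lt(max(abs((diag(60) + L) %*% V - Q)), 1e-10)

  # eigendecomposition inverse as an independent dense oracle
  eg <- eigen(diag(60) + L, symmetric = TRUE)
  V_oracle <- eg$vectors %*% diag(1 / eg$values) %*% t(eg$vectors) %*% Q
  expect_equal(as.vector(V), as.vector(V_oracle), tolerance = 1e-8)

  # kernel limits
  expect_equal(as.vector(node_diffusion(A, Q, lambda = 1e-9)), as.vector(Q),
               tolerance = 1e-6)
  expect_equal(max(abs(node_diffusion(A, Q * 0, lambda = 1))), 0)
  expect_error(node_diffusion(A, Q, lambda = 0), "positive")

  # K_L is symmetric positive definite (Cholesky succeeds)
  expect_no_error(chol(diag(60) + 1 * L))
})

test_that("isolated nodes retain their score under node diffusion", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A["a", "b"] <- A["b", "a"] <- 1
  V <- node_diffusion(A, c(a = 1, c = 2), lambda = 1)
  expect_equal(unname(V["c"]), 1)  # L row is identity for degree-0 nodes
})

test_that("edge diffusion matches the truncated heat-kernel series", {
  A <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  V <- c(a = 1, b = 2)
  ed <- edge_diffusion(A, V, beta = 0.3)
  W <- A %*% diag(1 / colSums(A))
  # direct power series oracle
  S_or <- matrix(0, 2, 2)
  P <- diag(2)
  for (t in 0:200) { S_or <- S_or + 0.3 * 0.7^t * P; P <- P %*% W }
  expect_equal(unname(ed$K_H), unname(S_or), tolerance = 1e-10)
  expect_equal(unname(ed$H), unname(S_or %*% diag(V)), tolerance = 1e-10)

  # beta = 1 collapses to the identity kernel
  ed1 <- edge_diffusion(A, V, beta = 1)
  expect_equal(unname(ed1$K_H), diag(2))
  expect_equal(unname(ed1$H), unname(diag(V)))
  expect_error(edge_diffusion(A, V, beta = 0), "0, 1")
  expect_error(edge_diffusion(A, V, beta = 1.5), "0, 1")
})

test_that("heat-kernel columns sum to one on connected graphs", {
  for (s in 1:3) {
    A <- random_connected_adjacency(40, 0.12, seed = s)
    ed <- edge_diffusion(A, setNames(runif(40), rownames(A)), beta = 0.3)
    expect_equal(unname(colSums(ed$K_H)), rep(1, 40), tolerance = 1e-10)
  }
})

test_that("DSD is a metric and the Gaussian similarity is bounded", {
  # H = I on 3 selected nodes: every off-diagonal L1 distance is 2
  H <- diag(3); dimnames(H) <- list(letters[1:3], letters[1:3])
  sel <- select_nodes_and_dsd(H, setNames(rep(1, 3), letters[1:3]),
                              direct_hits = letters[1:3], top_frac = 1)
  expect_equal(unname(sel$P["a", "b"]), 2)
  expect_equal(diag(sel$P), setNames(rep(0, 3), letters[1:3]))

  set.seed(9)
  for (i in 1:50) {
    n <- sample(6:14, 1)
    Hr <- matrix(runif(n * n), n, dimnames = list(paste0("g", 1:n),
                                                  paste0("g", 1:n)))
    res <- select_nodes_and_dsd(Hr, setNames(runif(n), rownames(Hr)),
                                direct_hits = rownames(Hr), top_frac = 1)
    P <- res$P
    expect_equal(P, t(P))
    expect_true(all(diag(P) == 0))
    # exhaustive triangle-inequality check over all triples
    worst <- max(vapply(seq_len(n), function(cc) {
      max(P - outer(P[, cc], P[cc, ], "+"))
    }, numeric(1)))
    expect_lte(worst, 1e-9)
    expect_true(all(res$S > 0 & res$S <= 1))
    expect_equal(diag(res$S), setNames(rep(1, n), rownames(Hr)))
  }
})

test_that("node selection unions direct hits with the top score fraction", {
  A <- random_connected_adjacency(100, 0.08, seed = 4)
  V <- setNames(sort(runif(100), decreasing = TRUE), rownames(A))
  sel <- select_nodes_and_dsd(edge_diffusion(A, V)$H, V,
                              direct_hits = rownames(A)[50], top_frac = 0.05)
  expect_true(rownames(A)[50] %in% sel$selected)
  expect_true(all(names(V)[1:5] %in% sel$selected))
  expect_error(select_nodes_and_dsd(diag(2), c(a = 1, b = 1), "a"), "3")
})

test_that("LOO-CV lambda selection separates planted from random hits", {
  spec <- synthetic_spec(n_genes = 250, n_modules = 5, seed = 17)
  net <- synth_multi_celltype_networks(spec)
  A <- graph_adjacency(net$graphs[[1]], nodes = net$genes)
  module_genes <- net$genes[net$labels[, 1] == 4][1:15]
  planted <- select_lambda_loocv(A, setNames(rep(2, 15), module_genes))
  expect_gt(max(planted$auroc$auroc), 0.85)
  expect_true(planted$lambda %in% c(0.1, 0.5, 1, 5, 10))

  set.seed(3)
  rnd <- select_lambda_loocv(A, setNames(rep(2, 40),
                                         sample(net$genes, 40)))
  expect_lt(abs(rnd$auroc$auroc[rnd$auroc$lambda == 1] - 0.5), 0.2)
  expect_error(select_lambda_loocv(A, setNames(2, net$genes[1])), "3 direct")
})

test_that("tie-breaking on equal AUROC picks the smaller lambda", {
  # a symmetric toy graph where several lambdas tie exactly
  A <- matrix(1, 4, 4) - diag(4)
  dimnames(A) <- list(letters[1:4], letters[1:4])
  res <- select_lambda_loocv(A, c(a = 1, b = 1, c = 1), grid = c(0.5, 1))
  expect_equal(res$lambda, min(res$auroc$lambda[res$auroc$auroc ==
                                                  max(res$auroc$auroc)]))
})

test_that("two-step diffusion bundles tidy results", {
  spec <- synthetic_spec(n_genes = 200, n_modules = 4, seed = 19)
  net <- synth_multi_celltype_networks(spec)
  hits <- net$genes[net$labels[, 1] == 2][1:10]
  dr <- diffuse_network(net$graphs[[1]], setNames(rep(2, 10), hits))
  td <- tidy(dr)
  expect_equal(sum(td$direct_hit), 10L)
  expect_true(all(td$diffused_score >= 0))
  expect_gte(glance(dr)$n_selected, 10L)
  expect_s3_class(autoplot(dr), "ggplot")
})
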