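mk_tss <- function(starts, genes) {
  tibble::tibble(chrom = "chr1", start = starts, end = starts + 1,
                 name = genes, score = NA_real_)
}

test_that("proximal network applies the strict purity cutoff and top-5% rule", {
  tss <- mk_tss(10000, "gA")
  hits <- tibble::tibble(chrom = "chr1", start = c(9000, 9100, 9200),
                         end = start + 10, name = c("TF1", "TF2", "TF3"),
                         score = c(0.95, 0.9, 0.92))
  net <- build_proximal_network(hits, tss, top_frac = 1)
  expect_setequal(net$from, c("TF1", "TF3"))   # 0.9 exactly is excluded

  # 100 candidate edges with distinct purities keep exactly 5
  tss100 <- mk_tss(seq(10000, by = 10000, length.out = 100),
                   sprintf("g%03d", 1:100))
  hits100 <- tibble::tibble(chrom = "chr1", start = tss100$start - 500,
                            end = start + 10, name = "TF1",
                            score = 0.90001 + (1:100) * 1e-4)
  top <- build_proximal_network(hits100, tss100, top_frac = 0.05)
  expect_equal(nrow(top), 5L)
  expect_equal(sort(top$score, decreasing = TRUE),
               sort(hits100$score, decreasing = TRUE)[1:5])

  # ties at the cutoff are all retained
  hits_tied <- dplyr::mutate(hits100, score = 0.95)
  expect_equal(nrow(build_proximal_network(hits_tied, tss100,
                                           top_frac = 0.05)), 100L)
})

test_that("distal edges need a loop joining a motif anchor to a TSS anchor", {
  tss <- mk_tss(201000, "gA")   # bin 40
  hits <- tibble::tibble(chrom = "chr1", start = c(21000, 201500),
                         end = start + 10, name = c("TF1", "TF2"),
                         score = c(0.95, 0.95))
  loops <- tibble::tibble(chrom = "chr1", bin1 = 4L, bin2 = 40L, count = 30,
                          d = 36L, p = 1e-5, q = 0.01)
  net <- build_distal_network(hits, tss, loops, top_frac = 1)
  expect_equal(net$from, "TF1")   # TF2 sits in the TSS anchor itself
  expect_equal(net$to, "gA")
  expect_equal(net$motif_bin, 4L)

  expect_equal(nrow(build_distal_network(hits, tss, loops[0, ])), 0L)
})

test_that("network merge unions provenance and drops self-loops", {
  ppi <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  prox <- tibble::tibble(from = "b", to = "a", score = 0.99,
                         provenance = "proximal")
  dist <- tibble::tibble(from = "c", to = "d", score = 0.95,
                         provenance = "distal")
  g <- merge_networks(ppi, prox, dist)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$provenance[g$edges$from == "a" & g$edges$to == "b"],
               "ppi,proximal")

  g2 <- merge_networks(tibble::tibble(from = c("a", "x"), to = c("b", "x")))
  expect_equal(nrow(g2$edges), 1L)   # self-loop dropped

  empty <- merge_networks()
  expect_equal(length(empty$nodes), 0L)

  A <- graph_adjacency(g)
  expect_true(isSymmetric(A))
  expect_equal(sum(A) / 2, 3)
})

test_that("UPGMA trees reflect the signal distances deterministically", {
  m <- rbind(A = c(0, 0), B = c(1, 0), C = c(10, 10))
  tree <- infer_tree_signal(m)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  # A and B merge first
  pair <- ape::extract.clade(tree, ape::getMRCA(tree, c("A", "B")))
  expect_setequal(pair$tip.label, c("A", "B"))

  # identical rows merge at height zero
  m2 <- rbind(A = c(1, 1), B = c(1, 1), C = c(5, 5))
  t2 <- infer_tree_signal(m2)
  h <- cophenetic(t2)
  expect_equal(h["A", "B"], 0)

  # invariant to row order
  t3 <- infer_tree_signal(m[c(3, 1, 2), ])
  expect_equal(cophenetic(t3)[rownames(cophenetic(tree)),
                              colnames(cophenetic(tree))],
               cophenetic(tree))

  expect_error(infer_tree_signal(rbind(A = 1:2, A = 3:4)), "duplicate")
  expect_error(infer_tree_signal(m[1, , drop = FALSE]), "at least 2")
})

test_that("interaction F-score matrix behaves at the extremes", {
  l1 <- tibble::tibble(chrom = "chr1", bin1 = 1:10, bin2 = 21:30)
  l2 <- l1
  l3 <- tibble::tibble(chrom = "chr1", bin1 = 41:50, bin2 = 61:70)
  res <- interaction_fscore_tree(list(a = l1, b = l2, c = l3))
  expect_equal(res$fscore["a", "b"], 1)
  expect_equal(res$fscore["a", "c"], 0)
  expect_equal(res$fscore, t(res$fscore))
  expect_setequal(res$tree$tip.label, c("a", "b", "c"))
})

test_that("Fowlkes-Mallows index is 1 for identical trees and bounded", {
  set.seed(1)
  m <- matrix(rnorm(60), nrow = 6,
              dimnames = list(paste0("ct", 1:6), NULL))
  tr <- infer_tree_signal(m)
  for (k in 2:4) {
    fm <- fowlkes_mallows(tr, tr, k = k, n_perm = 100, seed = 1)
    expect_equal(fm$index, 1)
    expect_true(fm$null_mean >= 0 && fm$null_mean <= 1)
  }
  expect_error(fowlkes_mallows(tr, tr, k = 1), "k must")
  expect_error(fowlkes_mallows(tr, tr, k = 6), "k must")

  # shuffled labels land near the permutation null
  set.seed(2)
  m2 <- m; rownames(m2) <- sample(rownames(m))
  tr2 <- infer_tree_signal(m2)
  fm2 <- fowlkes_mallows(tr, tr2, k = 3, n_perm = 300, seed = 2)
  expect_lt(abs(fm2$index - fm2$null_mean), 3 * max(fm2$null_sd, 0.05))
})
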