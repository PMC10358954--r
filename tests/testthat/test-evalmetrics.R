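test_that("distance-stratified correlation has the expected invariances", {
  ct <- build_cell_type(seed = 71, noise = 0.3)
  cc <- ct$cm$contacts
  n <- ct$spec$n_bins
  ident <- stratified_correlation_auc(cc, cc, n)
  expect_equal(ident$auc, 1)
  expect_true(all(abs(ident$curve$r[!is.na(ident$curve$r)] - 1) < 1e-12))

  shifted <- dplyr::mutate(cc, count = count + 100)
  expect_equal(stratified_correlation_auc(shifted, cc, n)$auc, 1)

  # independent predictions: permutation oracle, AUC near 0
  set.seed(3)
  shuffled <- dplyr::mutate(cc, count = sample(count))
  auc_null <- stratified_correlation_auc(shuffled, cc, n)$auc
  expect_lt(abs(auc_null), 0.1)
})

test_that("AUC is bounded and perfect only with perfect per-stratum correlation", {
  ct <- build_cell_type(seed = 72, noise = 0.5)
  cc <- ct$cm$contacts
  set.seed(1)
  noisy <- dplyr::mutate(cc, count = count * exp(rnorm(dplyr::n(), 0, 1)))
  res <- stratified_correlation_auc(noisy, cc, ct$spec$n_bins)
  expect_true(res$auc > -1 && res$auc < 1)
  expect_lt(res$auc, 1)
})

test_that("fold enrichment equals hand arithmetic and flags bad inputs", {
  expect_equal(enrichment_ratio(5, 10, 50, 1000), 10)
  expect_error(enrichment_ratio(11, 10, 50, 1000), "exceed")
  expect_true(is.na(enrichment_ratio(0, 0, 50, 1000)))

  gold <- tibble::tibble(chrom = "chr1", bin1 = 1:50, bin2 = 101:150)
  fe_self <- fold_enrichment(gold, gold, universe_size = 1000)
  expect_equal(fe_self$fold_enrichment, 1000 / 50)

  # random predictions are unenriched on average (resampling oracle)
  set.seed(4)
  universe <- all_candidate_pairs(80)
  universe$chrom <- "chr1"
  gold2 <- universe[sample(nrow(universe), 400), ]
  fe_rand <- replicate(30, {
    pred <- universe[sample(nrow(universe), 300), ]
    fold_enrichment(pred, gold2, nrow(universe))$fold_enrichment
  })
  expect_equal(mean(fe_rand), 1, tolerance = 0.1)
})

test_that("eQTL precision/recall counts set overlaps per distance bin", {
  pred <- tibble::tibble(snp_id = c("a", "b", "c"), gene_id = c("g1", "g2", "g3"),
                         distance = c(5e4, 1.5e5, 2.5e5))
  pr_same <- eqtl_precision_recall(pred, pred)
  filled <- pr_same[pr_same$n_pred > 0, ]
  expect_true(all(filled$precision == 1 & filled$recall == 1))

  other <- dplyr::mutate(pred, gene_id = c("x", "y", "z"))
  pr_disj <- eqtl_precision_recall(pred, other)
  expect_true(all(pr_disj$precision[pr_disj$n_pred > 0] == 0))
  expect_true(all(is.na(pr_disj$precision[pr_disj$n_pred == 0])))

  # brute-force set-intersection oracle on a random instance
  set.seed(5)
  mk <- function(n) tibble::tibble(
    snp_id = sample(sprintf("rs%d", 1:20), n, TRUE),
    gene_id = sample(sprintf("g%d", 1:10), n, TRUE),
    distance = sample(9e5, n)) |> dplyr::distinct(snp_id, gene_id, .keep_all = TRUE)
  p <- mk(40); e <- mk(40)
  pr <- eqtl_precision_recall(p, e)
  overlap <- sum(paste(p$snp_id, p$gene_id) %in% paste(e$snp_id, e$gene_id))
  expect_equal(sum(pr$precision * pr$n_pred, na.rm = TRUE), overlap)
  expect_equal(sum(pr$recall * pr$n_eqtl, na.rm = TRUE), overlap)
})

test_that("nearest-gene baseline minimizes distance with lower-coordinate ties", {
  snps <- tibble::tibble(chrom = "chr1", start = c(10000, 10500),
                         end = start + 1, name = c("s1", "s2"),
                         score = NA_real_)
  tss <- tibble::tibble(chrom = "chr1", start = c(9000, 12000),
                        end = start + 1, name = c("gA", "gB"),
                        score = NA_real_)
  nn <- nearest_gene_baseline(snps, tss)
  expect_equal(nn$gene_id[nn$snp_id == "s1"], "gA")
  expect_equal(nn$gene_id[nn$snp_id == "s2"], "gA")  # equidistant -> lower

  single <- nearest_gene_baseline(snps, tss[1, ])
  expect_true(all(single$gene_id == "gA"))

  off <- dplyr::mutate(snps, chrom = "chr2")
  expect_message(unmapped <- nearest_gene_baseline(off, tss), "no TSS")
  expect_true(all(is.na(unmapped$gene_id)))
})

test_that("expression comparison detects a planted interacting-gene effect", {
  set.seed(7)
  n <- 200
  tss <- tibble::tibble(chrom = "chr1",
                        start = seq(2500, by = 5000, length.out = 2 * n),
                        end = start + 1,
                        name = sprintf("g%03d", 1:(2 * n)), score = NA_real_)
  # loops touch the first n genes' bins
  loops <- tibble::tibble(chrom = "chr1", bin1 = 0:(n - 1), bin2 = 500 + 0:(n - 1),
                          count = 10, d = 500L, p = 1e-4, q = 1e-3)
  expr <- tibble::tibble(gene_id = tss$name,
                         rpkm = c(rlnorm(n, log(20), 1), rlnorm(n, log(10), 1)))
  res <- expression_interacting_vs_not(loops, tss, expr)
  expect_equal(res$n_interacting, n)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_log_interacting, res$mean_log_non_interacting)

  # identical distributions: no signal
  expr_null <- dplyr::mutate(expr, rpkm = rlnorm(2 * n, log(10), 1))
  res_null <- expression_interacting_vs_not(loops, tss, expr_null)
  expect_gt(res_null$p_value, 0.001)

  # pseudocount shields zero RPKM; empty groups are an error
  set.seed(8)
  expr_zero <- dplyr::mutate(expr,
                             rpkm = ifelse(runif(2 * n) < 0.3, 0, rpkm))
  res_zero <- expression_interacting_vs_not(loops, tss, expr_zero)
  expect_true(is.finite(res_zero$statistic))
  expect_error(expression_interacting_vs_not(loops[0, ], tss, expr), "non-empty")
})
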