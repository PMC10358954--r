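# Evaluation statistics: distance-stratified Pearson correlation and its
# AUC summary, fold enrichment against experimental gold standards, eQTL
# precision/recall with a nearest-gene baseline, and the
# interacting-vs-non-interacting gene expression comparison.

#' Distance-stratified Pearson correlation and its AUC
#'
#' Pearson r of predicted vs measured counts within every 5kb distance
#' stratum up to `max_bins`, over the full candidate universe (pairs absent
#' from either table count 0). The AUC summary is the mean of r over strata
#' with at least 3 pairs and non-degenerate variance (a trapezoid rule on the
#' uniform distance grid reduces to the mean).
#'
#' @param pred,truth Contact tables on the same chromosome.
#' @param n_bins Number of bins on the chromosome.
#' @param max_bins Maximum separation in bins (default 200).
#' @return An object of class `distance_correlation`: list with `curve`
#'   (tibble distance_bp / r / n_pairs) and `auc`.
#' @export
stratified_correlation_auc <- function(pred, truth, n_bins,
                                       max_bins = .MAX_BINS) {
  universe <- all_candidate_pairs(n_bins, max_bins)
  chrom <- if (nrow(truth) > 0) truth$chrom[[1]] else pred$chrom[[1]]
  df <- universe |>
    mutate(chrom = chrom) |>
    left_join(rename(pred, pred = "count"), by = c("chrom", "bin1", "bin2")) |>
    left_join(rename(truth, truth = "count"), by = c("chrom", "bin1", "bin2")) |>
    mutate(pred = ifelse(is.na(.data$pred), 0, .data$pred),
           truth = ifelse(is.na(.data$truth), 0, .data$truth),
           d = .data$bin2 - .data$bin1)
  curve <- df |>
    group_by(.data$d) |>
    summarise(n_pairs = dplyr::n(),
              r = if (dplyr::n() >= 3 && sd(.data$pred) > 0 && sd(.data$truth) > 0) {
                cor(.data$pred, .data$truth)
              } else {
                NA_real_
              },
              .groups = "drop") |>
    transmute(distance_bp = .data$d * .RES, r = .data$r,
              n_pairs = .data$n_pairs)
  skipped <- sum(is.na(curve$r))
  if (skipped > 0) {
    inform(paste0(skipped, " strata skipped (too few pairs or zero variance)"))
  }
  structure(list(curve = curve, auc = mean(curve$r, na.rm = TRUE)),
            class = "distance_correlation")
}

#' @export
tidy.distance_correlation <- function(x, ...) x$curve

#' @export
glance.distance_correlation <- function(x, ...) {
  tibble(auc = x$auc, n_strata = sum(!is.na(x$curve$r)))
}

#' @export
print.distance_correlation <- function(x, ...) {
  cat(sprintf("<distance_correlation> AUC = %.4f over %d strata\n", x$auc,
              sum(!is.na(x$curve$r))))
  invisible(x)
}

#' @export
autoplot.distance_correlation <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$distance_bp / 1000, y = .data$r)) +
    geom_line() +
    labs(x = "pair distance (kb)", y = "Pearson r",
         subtitle = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Fold enrichment of predictions over a gold standard
#'
#' `(q/k) / (m/S)`: the fraction of predictions overlapping the gold standard
#' relative to the gold standard's background rate in the candidate universe.
#'
#' @param q Overlap count (predictions also in the gold set).
#' @param k Number of predictions.
#' @param m Number of gold interactions mappable onto the universe.
#' @param S Size of the candidate universe.
#' @return The enrichment ratio; `NA` when k or m is 0.
#' @export
enrichment_ratio <- function(q, k, m, S) {
  if (S <= 0) abort("universe size must be positive")
  if (q > k) abort("overlap cannot exceed the number of predictions")
  if (q > m) abort("overlap cannot exceed the gold-standard size")
  if (k == 0 || m == 0) return(NA_real_)
  (q / k) / (m / S)
}

#' Fold enrichment of predicted pairs against gold-standard pairs
#'
#' @param pred,gold Pair tibbles keyed by (`chrom`, `bin1`, `bin2`); gold is
#'   assumed already mapped onto the candidate universe.
#' @param universe_size Number of candidate pairs S.
#' @return A tibble with `q`, `k`, `m`, `S` and `fold_enrichment`.
#' @export
fold_enrichment <- function(pred, gold, universe_size) {
  key <- function(df) distinct(df, .data$chrom, .data$bin1, .data$bin2)
  pk <- key(pred); gk <- key(gold)
  q <- nrow(inner_join(pk, gk, by = c("chrom", "bin1", "bin2")))
  tibble(q = q, k = nrow(pk), m = nrow(gk), S = universe_size,
         fold_enrichment = enrichment_ratio(q, nrow(pk), nrow(gk),
                                            universe_size))
}

#' eQTL precision and recall by SNP-TSS distance bin
#'
#' @param pred Predicted SNP-gene pairs: tibble (`snp_id`, `gene_id`,
#'   `distance`).
#' @param eqtl eQTL SNP-gene pairs, same columns.
#' @param breaks Distance bin edges in bp (default 100 kb bins up to 1 Mb).
#' @return Tibble per bin: `bin_lo`, `bin_hi`, `n_pred`, `n_eqtl`,
#'   `precision`, `recall` (NA on empty denominators).
#' @export
eqtl_precision_recall <- function(pred, eqtl,
                                  breaks = seq(0, 1e6, by = 1e5)) {
  bin_idx <- function(dist) cut(dist, breaks, right = FALSE, labels = FALSE)
  pk <- distinct(pred, .data$snp_id, .data$gene_id, .keep_all = TRUE) |>
    mutate(bin = bin_idx(.data$distance))
  ek <- distinct(eqtl, .data$snp_id, .data$gene_id, .keep_all = TRUE) |>
    mutate(bin = bin_idx(.data$distance))
  hit_key <- paste(ek$snp_id, ek$gene_id)
  pk$hit <- paste(pk$snp_id, pk$gene_id) %in% hit_key
  pred_key <- paste(pk$snp_id, pk$gene_id)
  ek$found <- hit_key %in% pred_key
  map(seq_len(length(breaks) - 1L), function(b) {
    np <- sum(pk$bin == b, na.rm = TRUE)
    ne <- sum(ek$bin == b, na.rm = TRUE)
    tibble(bin_lo = breaks[b], bin_hi = breaks[b + 1L], n_pred = np,
           n_eqtl = ne,
           precision = if (np > 0) sum(pk$hit[pk$bin == b], na.rm = TRUE) / np else NA_real_,
           recall = if (ne > 0) sum(ek$found[ek$bin == b], na.rm = TRUE) / ne else NA_real_)
  }) |>
    list_rbind()
}

#' Nearest-gene baseline for SNP-to-gene assignment
#'
#' Maps each SNP to the gene with the smallest distance between the SNP
#' position and the gene TSS; ties go to the lower-coordinate TSS. SNPs on
#' chromosomes without any TSS are left unmapped (with a message).
#'
#' @param snps Interval tibble of SNPs (`name` = SNP id, position = `start`).
#' @param tss Interval tibble of TSSs (`name` = gene id, position = `start`).
#' @return Tibble (`snp_id`, `gene_id`, `distance`).
#' @export
nearest_gene_baseline <- function(snps, tss) {
  out <- snps |>
    group_by(.data$chrom) |>
    group_modify(function(g, key) {
      cand <- tss[tss$chrom == key$chrom[[1]], ] |> arrange(.data$start)
      if (nrow(cand) == 0) {
        inform(paste0("no TSS on ", key$chrom[[1]], "; SNPs left unmapped"))
        return(tibble(snp_id = g$name, gene_id = NA_character_,
                      distance = NA_real_))
      }
      idx <- vapply(g$start, function(pos) {
        d <- abs(pos - cand$start)
        which(d == min(d))[1]  # cand sorted by coordinate, so ties -> lower
      }, integer(1))
      tibble(snp_id = g$name, gene_id = cand$name[idx],
             distance = abs(g$start - cand$start[idx]))
    }) |>
    ungroup()
  select(out, "snp_id", "gene_id", "distance")
}

#' Compare expression of loop-interacting vs non-interacting genes
#'
#' Genes whose TSS +/- 2500 bp window overlaps any anchor of a significant
#' interaction are "interacting"; the two groups' `log(RPKM + pseudocount)`
#' values are compared with a two-sample t-test.
#'
#' @param loops Significant-interaction tibble.
#' @param tss Interval tibble of TSSs (`name` = gene id).
#' @param expression Tibble (`gene_id`, `rpkm`), RPKM >= 0.
#' @param pseudocount Added before the log (default 0.1).
#' @return Tibble with `statistic`, `p_value`, `n_interacting`,
#'   `n_non_interacting`, and the group means of log expression.
#' @export
expression_interacting_vs_not <- function(loops, tss, expression,
                                          pseudocount = 0.1) {
  if (any(expression$rpkm < 0)) abort("RPKM values must be non-negative")
  anchor_bins <- unique(c(loops$bin1, loops$bin2))
  gene_bins <- tss_window_bins(tss)
  interacting_genes <- gene_bins |>
    filter(.data$bin %in% anchor_bins) |>
    pull(.data$gene_id) |>
    unique()
  expr <- expression |>
    mutate(interacting = .data$gene_id %in% interacting_genes,
           logx = log(.data$rpkm + pseudocount))
  if (all(expr$interacting) || !any(expr$interacting)) {
    abort("both interacting and non-interacting gene groups must be non-empty")
  }
  tt <- t.test(logx ~ interacting, data = expr)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         n_interacting = sum(expr$interacting),
         n_non_interacting = sum(!expr$interacting),
         mean_log_interacting = mean(expr$logx[expr$interacting]),
         mean_log_non_interacting = mean(expr$logx[!expr$interacting]))
}

# Bins overlapped by the +/-2500 bp TSS windows: tibble (gene_id, bin).
tss_window_bins <- function(tss, flank = 2500L) {
  map(seq_len(nrow(tss)), function(r) {
    lo <- max(0L, tss$start[r] - flank)
    hi <- tss$start[r] + flank  # window [tss-2500, tss+2500)
    tibble(gene_id = tss$name[r], bin = seq(bin_of(lo), bin_of(hi - 1L)))
  }) |>
    list_rbind() |>
    distinct()
}
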