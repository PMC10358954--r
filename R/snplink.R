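# Linking non-coding SNPs (and LD proxies) to genes through significant
# long-range interactions, and scoring genes for diffusion.

#' Expand lead SNPs with LD proxies
#'
#' @param snps Interval tibble of lead SNPs (`name` = SNP id).
#' @param ld Tibble (`lead`, `proxy`) of LD proxy ids; proxies inherit the
#'   lead's position record when they are not themselves in `snps`... proxies
#'   must carry their own positions, so `ld_positions` supplies them.
#' @param ld_positions Optional interval tibble of proxy positions.
#' @return Interval tibble of SNPs with columns `source` ("gwas" or "ld") and
#'   `lead_id`.
#' @export
expand_ld_proxies <- function(snps, ld = NULL, ld_positions = NULL) {
  leads <- snps |> mutate(source = "gwas", lead_id = .data$name)
  if (is.null(ld) || nrow(ld) == 0) return(leads)
  if (is.null(ld_positions)) abort("ld_positions needed when ld proxies are given")
  if (!all(ld$lead %in% snps$name)) abort("LD proxies must reference an existing lead SNP")
  proxies <- ld_positions |>
    inner_join(ld, by = c(name = "proxy")) |>
    mutate(source = "ld", lead_id = .data$lead) |>
    select(-"lead")
  bind_rows(leads, proxies)
}

#' Link SNPs to genes through significant interactions
#'
#' A SNP sits in bin `floor(pos / 5000)`; a gene claims every bin overlapping
#' its TSS window `[tss - 2500, tss + 2500)`. A SNP-gene pair is emitted
#' whenever the (snp bin, gene bin) pair is a significant loop; the loop's
#' q-value and the SNP-TSS distance are carried along. Each distinct
#' (SNP, gene) pair contributes once per supporting loop, de-duplicated to
#' its smallest q.
#'
#' @param snps Interval tibble of SNPs (`name` = SNP id).
#' @param loops Significant-interaction tibble (with `q`).
#' @param tss Interval tibble of TSSs (`name` = gene id).
#' @return Tibble (`snp_id`, `gene_id`, `snp_bin`, `gene_bin`, `q`,
#'   `distance`).
#' @export
link_snps_to_genes <- function(snps, loops, tss) {
  empty <- tibble(snp_id = character(), gene_id = character(),
                  snp_bin = integer(), gene_bin = integer(), q = numeric(),
                  distance = numeric())
  if (nrow(loops) == 0 || nrow(snps) == 0 || nrow(tss) == 0) return(empty)
  gene_bins <- tss_window_bins(tss) |> rename(gene_bin = "bin")
  tss_pos <- tibble(gene_id = tss$name, tss_start = tss$start)
  snp_tbl <- tibble(snp_id = snps$name, snp_pos = snps$start,
                    snp_bin = bin_of(snps$start))
  loop_keys <- loops |>
    select("bin1", "bin2", "q")
  both <- bind_rows(loop_keys,
                    tibble(bin1 = loop_keys$bin2, bin2 = loop_keys$bin1,
                           q = loop_keys$q))
  out <- snp_tbl |>
    inner_join(both, by = c(snp_bin = "bin1"), relationship = "many-to-many") |>
    rename(gene_bin = "bin2") |>
    inner_join(gene_bins, by = "gene_bin", relationship = "many-to-many") |>
    inner_join(tss_pos, by = "gene_id", relationship = "many-to-many") |>
    mutate(distance = abs(.data$snp_pos - .data$tss_start)) |>
    group_by(.data$snp_id, .data$gene_id) |>
    slice_min(.data$q, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("snp_id", "gene_id", "snp_bin", "gene_bin", "q", "distance") |>
    arrange(.data$snp_id, .data$gene_id)
  out
}

#' Score genes by their significant SNP interactions
#'
#' A gene's score is the mean of `-log10(q)` over its SNP-gene pairs
#' (q clamped at 1e-300); such genes are the "direct hits" seeding network
#' diffusion. Genes without SNP loops score 0 and are not direct hits.
#'
#' @param pairs Output of [link_snps_to_genes()].
#' @param genes Optional gene universe; genes without pairs get score 0.
#' @return Tibble (`gene_id`, `score`, `direct_hit`, `n_snps`).
#' @export
score_genes <- function(pairs, genes = NULL) {
  scored <- pairs |>
    group_by(.data$gene_id) |>
    summarise(score = mean(-log10(pmax(.data$q, 1e-300))),
              n_snps = dplyr::n(), .groups = "drop") |>
    mutate(direct_hit = TRUE)
  if (!is.null(genes)) {
    scored <- tibble(gene_id = genes) |>
      left_join(scored, by = "gene_id") |>
      mutate(score = ifelse(is.na(.data$score), 0, .data$score),
             n_snps = ifelse(is.na(.data$n_snps), 0L, .data$n_snps),
             direct_hit = !is.na(.data$direct_hit) & .data$direct_hit)
  }
  select(scored, "gene_id", "score", "direct_hit", "n_snps")
}
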