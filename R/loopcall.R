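# Distance-stratified binomial test for significant interactions. Within
# each 5kb distance stratum up to 1Mb the background is uniform: every
# candidate pair at that distance is equally likely to receive each of the
# n_d observed interactions, so a pair's count k is tested against
# Binomial(n_d, 1/#candidates) and corrected with Benjamini-Hochberg.

#' Distance-stratified binomial p-values for contact pairs
#'
#' Counts are rounded half-to-even to integers (predicted counts are real).
#' For each distance stratum d the candidate universe is every bin pair at
#' that separation on the chromosome, `m_d` = 1 / #candidates and `n_d` = the
#' stratum's total rounded count; each observed pair gets the upper-tail
#' probability P(K >= k | n_d, m_d).
#'
#' @param contacts Contact table (`chrom`, `bin1`, `bin2`, `count`).
#' @param n_bins Number of bins on the chromosome (defines the candidate
#'   universe).
#' @param max_bins Maximum pair separation in bins (default 200 = 1 Mb).
#' @return The observed (nonzero after rounding) pairs with columns `k`
#'   (integer count), `d` (separation in bins), `n_d`, `m_d` and `p`.
#' @export
binomial_pvalues <- function(contacts, n_bins, max_bins = .MAX_BINS) {
  if (any(contacts$count < 0)) abort("counts must be non-negative")
  df <- contacts |>
    mutate(d = .data$bin2 - .data$bin1, k = round(.data$count)) |>
    filter(.data$d >= 1L, .data$d <= max_bins)
  df |>
    group_by(.data$chrom, .data$d) |>
    group_modify(function(g, key) {
      n_cand <- n_bins - key$d[[1]]
      if (n_cand <= 0) return(g[0, ])
      m_d <- 1 / n_cand
      n_d <- sum(g$k)
      mutate(g, n_d = n_d, m_d = m_d,
             p = binom_upper_tail(.data$k, n_d, m_d))
    }) |>
    ungroup() |>
    filter(.data$k > 0) |>
    select("chrom", "bin1", "bin2", "count", "k", "d", "n_d", "m_d", "p") |>
    arrange(.data$chrom, .data$bin1, .data$bin2)
}

# Upper-tail binomial probability P(K >= k | n, m); k = 0 gives 1.
binom_upper_tail <- function(k, n, m) {
  ifelse(k <= 0, 1, pbinom(k - 1, size = n, prob = m, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH: `q_(i) = min_{j >= i} p_(j) * M / j`, capped at 1, mapped back
#' to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significant interactions at an FDR threshold
#'
#' Applies BH within each distance stratum (or pooled across strata with
#' `global_fdr = TRUE`) and retains records with q-value below `alpha`.
#'
#' @param tested Output of [binomial_pvalues()].
#' @param alpha FDR threshold (default 0.05, strict inequality).
#' @param global_fdr Pool the BH correction across strata instead of within
#'   each stratum.
#' @return Tibble of significant records (`chrom`, `bin1`, `bin2`, `count`,
#'   `d`, `p`, `q`).
#' @export
call_significant <- function(tested, alpha = 0.05, global_fdr = FALSE) {
  grouped <- if (global_fdr) {
    tested |> group_by(.data$chrom)
  } else {
    tested |> group_by(.data$chrom, .data$d)
  }
  grouped |>
    mutate(q = bh_qvalues(.data$p)) |>
    ungroup() |>
    filter(.data$q < alpha) |>
    select("chrom", "bin1", "bin2", "count", "d", "p", "q") |>
    arrange(.data$chrom, .data$bin1, .data$bin2)
}

#' Full loop-calling pipeline on a contact table
#'
#' @inheritParams binomial_pvalues
#' @inheritParams call_significant
#' @return Significant-interaction tibble (see [call_significant()]).
#' @export
call_loops <- function(contacts, n_bins, alpha = 0.05, max_bins = .MAX_BINS,
                       global_fdr = FALSE) {
  call_significant(binomial_pvalues(contacts, n_bins, max_bins), alpha,
                   global_fdr)
}
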