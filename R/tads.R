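# Directionality-index TAD calling. The DI of a bin contrasts its upstream
# and downstream contact mass inside a 2Mb window with a chi-square-like
# statistic; domains are segmented at sign transitions from a sustained
# negative run to a sustained positive run.

#' Per-bin directionality index
#'
#' For bin i with upstream contact mass A (to bins in (i-W, i)) and
#' downstream mass B (to bins in (i, i+W)), `DI = sign(B - A) * ((A-E)^2/E +
#' (B-E)^2/E)` with `E = (A+B)/2`; bins with A = B or E = 0 get 0. Windows
#' are truncated at chromosome edges.
#'
#' @param contacts Contact table.
#' @param n_bins Number of bins on the chromosome.
#' @param window_bp Window size in bp (default 2 Mb).
#' @return Tibble (`chrom`, `bin`, `di`).
#' @export
directionality_index <- function(contacts, n_bins, window_bp = 2e6) {
  w_bins <- as.integer(window_bp %/% .RES)
  chrom <- if (nrow(contacts) > 0) contacts$chrom[[1]] else "chr1"
  A <- numeric(n_bins)
  B <- numeric(n_bins)
  keep <- contacts$bin2 - contacts$bin1 < w_bins &
    contacts$bin1 < n_bins & contacts$bin2 < n_bins
  cc <- contacts[keep, ]
  # pair (b1, b2): downstream mass for b1, upstream mass for b2
  for (r in seq_len(nrow(cc))) {
    B[cc$bin1[r] + 1L] <- B[cc$bin1[r] + 1L] + cc$count[r]
    A[cc$bin2[r] + 1L] <- A[cc$bin2[r] + 1L] + cc$count[r]
  }
  E <- (A + B) / 2
  di <- numeric(n_bins)
  ok <- E > 0 & A != B
  di[ok] <- sign(B[ok] - A[ok]) *
    ((A[ok] - E[ok])^2 / E[ok] + (B[ok] - E[ok])^2 / E[ok])
  tibble(chrom = chrom, bin = seq_len(n_bins) - 1L, di = di)
}

#' Segment a DI profile into TADs
#'
#' A domain boundary is placed at the first bin of a positive DI run that
#' directly follows a negative run, requiring both runs to have length >=
#' `min_run`. Chromosome ends act as implicit boundaries; domains shorter
#' than 3 bins are dropped.
#'
#' @param di DI tibble from [directionality_index()].
#' @param min_run Minimum run length on each side of a transition (default 3).
#' @return TAD tibble (`chrom`, `start`, `end` in bp), sorted and
#'   non-overlapping, with the boundary bin indices in attribute
#'   `boundaries`.
#' @export
call_tads <- function(di, min_run = 3L) {
  s <- sign(di$di)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  boundaries <- integer(0)
  for (r in seq_along(runs$values)[-1]) {
    if (runs$values[r] == 1 && runs$values[r - 1] == -1 &&
        runs$lengths[r] >= min_run && runs$lengths[r - 1] >= min_run) {
      boundaries <- c(boundaries, di$bin[starts[r]])
    }
  }
  n_bins <- nrow(di)
  cuts <- unique(c(0L, boundaries, n_bins))
  doms <- tibble(chrom = di$chrom[[1]],
                 start = head(cuts, -1) * .RES,
                 end = tail(cuts, -1) * .RES) |>
    filter(.data$end - .data$start >= 3L * .RES)
  if (length(boundaries) == 0) doms <- doms[0, ]
  attr(doms, "boundaries") <- boundaries
  doms
}

#' Reciprocal best-match Jaccard similarity of two TAD sets
#'
#' Each TAD in one set is matched to its highest base-pair Jaccard partner in
#' the other set; the matched coefficients are averaged within each
#' direction and the two directional means are averaged. An empty set against
#' a non-empty one scores 0; two empty sets score 1.
#'
#' @param set1,set2 TAD tibbles (`chrom`, `start`, `end`) on one chromosome.
#' @return Similarity in `[0, 1]`.
#' @export
tad_jaccard_similarity <- function(set1, set2) {
  if (nrow(set1) == 0 && nrow(set2) == 0) return(1)
  if (nrow(set1) == 0 || nrow(set2) == 0) return(0)
  jac <- function(a0, a1, b0, b1) {
    inter <- pmax(0, pmin(a1, b1) - pmax(a0, b0))
    uni <- (a1 - a0) + (b1 - b0) - inter
    ifelse(uni > 0, inter / uni, 0)
  }
  best <- function(from, to) {
    mean(vapply(seq_len(nrow(from)), function(r) {
      max(jac(from$start[r], from$end[r], to$start, to$end))
    }, numeric(1)))
  }
  (best(set1, set2) + best(set2, set1)) / 2
}

#' Plot a directionality-index profile
#'
#' @param di DI tibble from [directionality_index()].
#' @param boundaries Optional boundary bin indices to mark.
#' @return A ggplot.
#' @export
plot_directionality_index <- function(di, boundaries = NULL) {
  p <- ggplot(di, aes(x = .data$bin, y = .data$di)) +
    geom_col(width = 1) +
    labs(x = "bin (5 kb)", y = "directionality index") +
    theme_minimal()
  if (!is.null(boundaries)) {
    p <- p + ggplot2::geom_vline(xintercept = boundaries, linetype = "dashed",
                                 colour = "red")
  }
  p
}
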