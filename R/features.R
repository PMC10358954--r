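# Pair-feature construction: replicate collapsing, 1-D k-means
# discretization into 20 levels, motif-hit counting, and assembly of the
# 31-dimensional pair representation (10 region1 + 10 window + 10 region2
# features + genomic distance).

#' Depth-normalize replicate tracks and collapse by the per-bin median
#'
#' Each replicate is scaled to counts-per-million (value * 1e6 / total
#' signal), then replicates are collapsed bin-wise by the median.
#'
#' @param tracks List of signal tibbles (`chrom`, `bin`, `value`), one per
#'   replicate, on the same bin grid.
#' @return A single signal tibble.
#' @export
normalize_and_collapse <- function(tracks) {
  if (length(tracks) == 0) abort("need at least one replicate")
  scaled <- map(tracks, function(tr) {
    tot <- sum(tr$value)
    if (tot == 0) abort("all-zero replicate cannot be depth-normalized")
    mutate(tr, value = .data$value * 1e6 / tot)
  })
  bind_rows(scaled) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(value = median(.data$value), .groups = "drop") |>
    arrange(.data$chrom, .data$bin)
}

#' Fit a 1-D k-means discretization model
#'
#' Clusters the per-bin values of one track into `k` levels with k-means;
#' cluster centers are sorted so level 0 is the lowest-signal level. The same
#' fitted model is meant to be applied to every cell type (fit on the
#' training cell type, apply everywhere) so that levels are comparable across
#' cell types. If the track has fewer than `k` distinct values, `k` is
#' reduced to that count.
#'
#' @param track Signal tibble.
#' @param k Number of levels (default 20).
#' @param seed Integer seed for the k-means initialization.
#' @return An object of class `discretization_model` with sorted `centers`.
#' @export
fit_discretization <- function(track, k = 20L, seed = 1L) {
  v <- track$value
  if (length(v) == 0) abort("cannot discretize an empty track")
  k_eff <- min(k, length(unique(v)))
  centers <- if (k_eff == 1L) {
    v[[1]]
  } else {
    set.seed(seed)
    sort(as.vector(kmeans(v, centers = k_eff, nstart = 5, iter.max = 100)$centers))
  }
  structure(list(centers = centers, k = k_eff), class = "discretization_model")
}

#' Assign discrete levels with a fitted discretization model
#'
#' @param model A `discretization_model`.
#' @param values Numeric vector or signal tibble.
#' @return Integer levels in `[0, k-1]` (nearest center; midpoint ties go to
#'   the lower level); a signal tibble in, a signal tibble of levels out.
#' @export
apply_discretization <- function(model, values) {
  if (is.data.frame(values)) {
    return(mutate(values, value = as.numeric(apply_discretization(model, values$value))))
  }
  cen <- model$centers
  if (length(cen) == 1L) return(rep(0L, length(values)))
  mid <- (head(cen, -1) + tail(cen, -1)) / 2
  findInterval(values, mid, left.open = TRUE)
}

#' Count motif hits per 5 kb bin above a purity threshold
#'
#' @param hits Interval tibble of motif hits with purity scores in `score`.
#' @param purity_min Keep hits with score strictly greater than this
#'   (default 0.50).
#' @param n_bins Number of bins of the output track.
#' @param chrom Chromosome to count on.
#' @return A signal tibble of per-bin hit counts (hit assigned to the bin of
#'   its start; half-open bins, so a start at exactly 5000 lands in bin 1).
#' @export
motif_bin_counts <- function(hits, purity_min = 0.50, n_bins, chrom = "chr1") {
  kept <- hits |> filter(.data$chrom == !!chrom, .data$score > purity_min)
  v <- numeric(n_bins)
  if (nrow(kept) > 0) {
    b <- bin_of(kept$start)
    b <- b[b < n_bins]
    tb <- table(b)
    v[as.integer(names(tb)) + 1L] <- as.vector(tb)
  }
  signal_from_vector(v, chrom)
}

#' Build the 31-dimensional pair feature table
#'
#' For each candidate bin pair (i, j) with 1 <= j - i <= `max_bins`, emits 10
#' region1 features (discretized ChIP/DNase levels and motif counts at bin
#' i), 10 window features, 10 region2 features (at bin j) and the genomic
#' distance in bp. The window feature of a ChIP/DNase track is the mean of
#' the discrete levels over the intervening bins i+1..j-1; for a motif track
#' it is the total motif count in the window divided by the number of window
#' bins. Adjacent pairs (j = i + 1) have no intervening bin and use the mean
#' of the two anchor values.
#'
#' @param chip_levels Named list of discretized ChIP/DNase signal tibbles
#'   (levels as values).
#' @param motif_counts Named list of motif count signal tibbles.
#' @param chrom Chromosome name.
#' @param n_bins Number of bins covered.
#' @param pairs Optional tibble (`bin1`, `bin2`) restricting the pairs;
#'   default all candidate pairs at 1..`max_bins` bin separation. Pairs
#'   outside [1, `max_bins`] bins are dropped silently.
#' @param max_bins Maximum pair separation in bins (default 200 = 1 Mb).
#' @return A tibble with `chrom`, `bin1`, `bin2`, one column per feature
#'   (`<track>_r1`, `<track>_w`, `<track>_r2`) and `distance` (bp).
#' @export
build_pair_features <- function(chip_levels, motif_counts, chrom = "chr1",
                                n_bins, pairs = NULL, max_bins = .MAX_BINS) {
  if (is.null(pairs)) pairs <- all_candidate_pairs(n_bins, max_bins)
  # canonicalize to bin1 < bin2: a swapped pair yields the mirrored region
  # blocks with the same window and distance
  pairs <- tibble(bin1 = pmin(pairs$bin1, pairs$bin2),
                  bin2 = pmax(pairs$bin1, pairs$bin2))
  d <- pairs$bin2 - pairs$bin1
  keep <- d >= 1L & d <= max_bins
  pairs <- pairs[keep, ]
  d <- d[keep]
  i <- pairs$bin1
  j <- pairs$bin2

  window_mean <- function(v) {
    cs <- c(0, cumsum(v))
    # sum over 0-based bins (i+1)..(j-1); cs is 1-based cumulative
    w <- (cs[j + 1L] - cs[i + 2L]) / pmax(d - 1L, 1L)
    adj <- d == 1L
    w[adj] <- (v[i[adj] + 1L] + v[j[adj] + 1L]) / 2
    w
  }
  window_rate <- function(v) {
    cs <- c(0, cumsum(v))
    w <- (cs[j + 1L] - cs[i + 2L]) / pmax(d - 1L, 1L)
    adj <- d == 1L
    w[adj] <- (v[i[adj] + 1L] + v[j[adj] + 1L]) / 2
    w
  }

  feats <- list()
  all_tracks <- c(chip_levels, motif_counts)
  is_motif <- c(rep(FALSE, length(chip_levels)), rep(TRUE, length(motif_counts)))
  vecs <- map(all_tracks, signal_vector, chrom = chrom, n_bins = n_bins)
  for (t in seq_along(vecs)) {
    nm <- names(all_tracks)[[t]]
    v <- vecs[[t]]
    feats[[paste0(nm, "_r1")]] <- v[i + 1L]
    feats[[paste0(nm, "_w")]] <- if (is_motif[[t]]) window_rate(v) else window_mean(v)
    feats[[paste0(nm, "_r2")]] <- v[j + 1L]
  }
  # fixed column order: all region1, all window, all region2, then distance
  ord <- c(paste0(names(all_tracks), "_r1"), paste0(names(all_tracks), "_w"),
           paste0(names(all_tracks), "_r2"))
  bind_cols(tibble(chrom = chrom, bin1 = i, bin2 = j),
            as_tibble(feats)[ord],
            tibble(distance = as.numeric(d) * .RES))
}

#' Attach observed counts to a pair feature table
#'
#' @param features Pair feature table.
#' @param contacts Contact table; pairs absent from it get count 0.
#' @return The feature table with a `count` column.
#' @export
add_counts <- function(features, contacts) {
  features |>
    left_join(contacts, by = c("chrom", "bin1", "bin2")) |>
    mutate(count = ifelse(is.na(.data$count), 0, .data$count))
}
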