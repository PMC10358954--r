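# Readers and writers for the plain-text formats the pipeline consumes:
# bedGraph signal tracks, 5kb pair-count TSVs, weighted edge lists, and BED
# intervals. Coordinates are 0-based half-open everywhere; bin index =
# floor(position / 5000).

#' Convert a base-pair position to a 5 kb bin index
#'
#' @param pos Integer vector of 0-based genomic positions.
#' @param resolution Bin width in bp (default 5000).
#' @return Integer vector of bin indices (`floor(pos / resolution)`).
#' @export
bin_of <- function(pos, resolution = 5000L) {
  as.integer(floor(pos / resolution))
}

#' Read a bedGraph signal track into 5 kb bins
#'
#' Aggregates a 4-column bedGraph (chrom, start, end, value) into fixed-width
#' bins by the length-weighted mean of overlapping records. Bins not covered
#' by any record get value 0.
#'
#' @param path Path to a bedGraph file (no track lines).
#' @param resolution Bin width in bp (default 5000).
#' @param label Assay name attached to the result.
#' @param cell_type Cell type attached to the result.
#' @return A tibble with columns `chrom`, `bin`, `value` and attributes
#'   `label` and `cell_type`; one row per covered bin plus zero-filled gaps up
#'   to the last covered bin of each chromosome.
#' @export
read_signal_track <- function(path, resolution = 5000L, label = NA_character_,
                              cell_type = NA_character_) {
  raw <- tryCatch(
    read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "value"),
               colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) abort(paste0("malformed bedGraph '", path, "': ", conditionMessage(e)))
  )
  bad <- which(!is.finite(raw$start) | !is.finite(raw$end) | raw$start >= raw$end)
  if (length(bad) > 0) {
    abort(paste0("malformed bedGraph record at line ", bad[1], " of '", path, "'"))
  }
  out <- raw |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$start)
      if (any(df$start[-1] < df$end[-nrow(df)])) {
        abort(paste0("overlapping bedGraph records on ", key$chrom[[1]]))
      }
      bin_signal_records(df$start, df$end, df$value, resolution)
    }) |>
    ungroup()
  attr(out, "label") <- label
  attr(out, "cell_type") <- cell_type
  attr(out, "resolution") <- as.integer(resolution)
  out
}

# Length-weighted binning of (start, end, value) records on one chromosome.
bin_signal_records <- function(start, end, value, resolution) {
  n_bins <- as.integer(ceiling(max(end) / resolution))
  acc <- numeric(n_bins)
  for (r in seq_along(start)) {
    b0 <- bin_of(start[r], resolution)
    b1 <- bin_of(end[r] - 1, resolution)
    for (b in b0:b1) {
      lo <- max(start[r], b * resolution)
      hi <- min(end[r], (b + 1) * resolution)
      acc[b + 1L] <- acc[b + 1L] + (hi - lo) * value[r]
    }
  }
  tibble(bin = seq_len(n_bins) - 1L, value = acc / resolution)
}

#' Read a Hi-C pair-count TSV into a contact table
#'
#' Expects whitespace/tab-separated columns chrom, start1, start2, count with
#' starts that are multiples of the resolution. Pairs are canonicalized to
#' `bin1 < bin2`; duplicates (including mirrored duplicates) are summed.
#'
#' @param path Path to the pairs file (no header).
#' @param resolution Bin width in bp (default 5000).
#' @return A contact table: tibble with columns `chrom`, `bin1`, `bin2`,
#'   `count`, `bin1 < bin2`, counts >= 0.
#' @export
read_pairs <- function(path, resolution = 5000L) {
  if (file.size(path) == 0) {
    return(tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                  count = numeric()))
  }
  raw <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start1", "start2", "count"),
                    colClasses = c("character", "numeric", "numeric", "numeric"))
  if (any(raw$start1 %% resolution != 0 | raw$start2 %% resolution != 0)) {
    abort("pair start coordinates must be multiples of the resolution")
  }
  if (any(raw$count < 0)) abort("negative contact count in pairs file")
  raw |>
    mutate(bin1 = pmin(bin_of(.data$start1, resolution), bin_of(.data$start2, resolution)),
           bin2 = pmax(bin_of(.data$start1, resolution), bin_of(.data$start2, resolution))) |>
    filter(.data$bin1 != .data$bin2) |>
    count_pairs()
}

count_pairs <- function(df) {
  df |>
    group_by(.data$chrom, .data$bin1, .data$bin2) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$bin1, .data$bin2)
}

#' Write a contact table as a pairs TSV
#'
#' @param contacts Contact table (`chrom`, `bin1`, `bin2`, `count`).
#' @param path Output path.
#' @param resolution Bin width in bp.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(contacts, path, resolution = 5000L) {
  out <- contacts |>
    transmute(.data$chrom, start1 = .data$bin1 * resolution,
              start2 = .data$bin2 * resolution, .data$count)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list, keeping high-confidence edges
#'
#' Edges with score strictly greater than `min_score` are retained;
#' self-loops are dropped. Intended for e.g. STRING protein-protein
#' interaction exports (confidence > 0.95 for a high-confidence network).
#'
#' @param path TSV with columns nodeA, nodeB, score (no header).
#' @param min_score Retain edges with score strictly above this value.
#' @return Tibble with columns `from`, `to`, `score`, undirected (one row per
#'   unordered pair, nodes sorted within a row).
#' @export
read_edge_list <- function(path, min_score = 0.95) {
  raw <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    col.names = c("from", "to", "score"),
                    colClasses = c("character", "character", "character"))
  score <- suppressWarnings(as.numeric(raw$score))
  if (anyNA(score)) abort("non-numeric score in edge list")
  tibble(from = pmin(raw$from, raw$to), to = pmax(raw$from, raw$to),
         score = score) |>
    filter(.data$from != .data$to, .data$score > min_score) |>
    distinct(.data$from, .data$to, .keep_all = TRUE) |>
    arrange(.data$from, .data$to)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file; optional 4th (name) and 5th (score) columns are
#'   captured when present.
#' @return Tibble `chrom`, `start`, `end`, `name`, `score` in file order,
#'   0-based half-open.
#' @export
read_intervals <- function(path) {
  raw <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.numeric(raw[[2]]),
                end = as.numeric(raw[[3]]),
                name = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
                score = if (ncol(raw) >= 5) as.numeric(raw[[5]]) else NA_real_)
  if (any(out$start >= out$end)) {
    abort(paste0("interval with start >= end at line ",
                 which(out$start >= out$end)[1]))
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  if (!all(is.na(intervals$name %||% NA))) cols <- c(cols, "name")
  if ("score" %in% names(intervals) && !all(is.na(intervals$score))) {
    if (!"name" %in% cols) intervals$name <- "."
    cols <- unique(c(cols, "name", "score"))
  }
  write.table(intervals[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Dense per-bin value vector for one chromosome of a signal track,
# zero-filled to n_bins.
signal_vector <- function(track, chrom, n_bins) {
  v <- numeric(n_bins)
  sub <- track[track$chrom == chrom & track$bin < n_bins, ]
  v[sub$bin + 1L] <- sub$value
  v
}

# Tibble form of a dense per-bin vector.
signal_from_vector <- function(values, chrom = "chr1") {
  tibble(chrom = chrom, bin = seq_along(values) - 1L, value = as.numeric(values))
}
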