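# Local 1Mb-segment random-forest regression of contact counts. A separate
# forest is trained for every non-overlapping 1Mb tile of the chromosome on
# all pairs touching the tile; predictions for pairs spanning two tiles
# average the two forests. A chromosome-wide single forest serves as the
# global baseline, and copying the training cell type's measured counts is
# the transfer-count baseline.

segment_of <- function(bin, segment_bins = .SEGMENT_BP %/% .RES) {
  as.integer(bin %/% segment_bins)
}

#' Assign pairs to the 1 Mb training segments they touch
#'
#' A pair is assigned to every segment containing one of its anchor bins, so
#' it lands in one segment (both anchors inside) or two (spanning pair).
#'
#' @param features Pair feature table (needs `bin1`, `bin2`).
#' @param segment_bins Segment width in bins (default 200 = 1 Mb).
#' @return Tibble (`row`, `segment`): one row per (pair, segment) assignment.
#' @export
assign_training_pairs <- function(features, segment_bins = 200L) {
  s1 <- segment_of(features$bin1, segment_bins)
  s2 <- segment_of(features$bin2, segment_bins)
  tibble(row = rep(seq_len(nrow(features)), 2L), segment = c(s1, s2)) |>
    distinct() |>
    arrange(.data$segment, .data$row)
}

feature_columns <- function(features) {
  setdiff(names(features), c("chrom", "bin1", "bin2", "count"))
}

# One regression forest (or a constant fallback for degenerate segments).
fit_forest <- function(x, y, trees, mtry, seed) {
  if (nrow(x) < 2L || length(unique(y)) == 1L) {
    return(structure(list(constant = mean(y)), class = "constant_model"))
  }
  ranger::ranger(x = x, y = y, num.trees = trees, mtry = min(mtry, ncol(x)),
                 seed = seed, num.threads = 1L, verbose = FALSE)
}

predict_forest <- function(model, x) {
  if (inherits(model, "constant_model")) return(rep(model$constant, nrow(x)))
  predict(model, data = x, num.threads = 1L, verbose = FALSE)$predictions
}

#' Train the local 1 Mb-segment forest ensemble
#'
#' @param features Pair feature table with a `count` target column.
#' @param trees Trees per forest (default 100).
#' @param mtry Features per split (default `ceiling(p / 3)`).
#' @param seed Integer seed (each segment forest gets a derived sub-seed).
#' @param segment_bins Segment width in bins (default 200 = 1 Mb).
#' @param cell_type Optional training cell type recorded in metadata.
#' @return An object of class `lhicreg_ensemble`.
#' @export
train_local <- function(features, trees = 100L, mtry = NULL, seed = 1L,
                        segment_bins = 200L, cell_type = NA_character_) {
  if (!"count" %in% names(features)) abort("features must carry a count target")
  if (nrow(features) == 0) abort("empty training table")
  cols <- feature_columns(features)
  mtry <- mtry %||% ceiling(length(cols) / 3)
  assign <- assign_training_pairs(features, segment_bins)
  x_all <- as.data.frame(features[cols])
  models <- assign |>
    group_by(.data$segment) |>
    group_map(function(df, key) {
      fit_forest(x_all[df$row, , drop = FALSE], features$count[df$row],
                 trees, mtry, seed = seed + key$segment[[1]])
    })
  segs <- sort(unique(assign$segment))
  names(models) <- as.character(segs)
  structure(
    list(models = models, segments = segs, feature_names = cols,
         trees = trees, mtry = mtry, seed = seed, segment_bins = segment_bins,
         cell_type = cell_type, global = FALSE),
    class = "lhicreg_ensemble")
}

#' Train the chromosome-wide single-forest baseline
#'
#' Same forest settings as [train_local()] but one model on all pairs of the
#' chromosome, ignoring segment locality.
#'
#' @inheritParams train_local
#' @return An `lhicreg_ensemble` with a single global model.
#' @export
train_global <- function(features, trees = 100L, mtry = NULL, seed = 1L,
                         cell_type = NA_character_) {
  if (!"count" %in% names(features)) abort("features must carry a count target")
  cols <- feature_columns(features)
  mtry <- mtry %||% ceiling(length(cols) / 3)
  model <- fit_forest(as.data.frame(features[cols]), features$count, trees,
                      mtry, seed)
  structure(
    list(models = list(global = model), segments = integer(),
         feature_names = cols, trees = trees, mtry = mtry, seed = seed,
         segment_bins = NA_integer_, cell_type = cell_type, global = TRUE),
    class = "lhicreg_ensemble")
}

#' Predict contact counts for a test cell type
#'
#' Pairs inside one segment use that segment's forest; pairs spanning two
#' segments use the arithmetic mean of the two forests. Pairs hitting a
#' segment with no trained model fall back to the nearest trained segment
#' (with a warning). Negative predictions are clamped to zero.
#'
#' @param ensemble An `lhicreg_ensemble` from [train_local()] or
#'   [train_global()].
#' @param features Pair feature table for the test cell type (same feature
#'   columns as training).
#' @return A contact table of predicted counts.
#' @export
predict_counts <- function(ensemble, features) {
  if (!all(ensemble$feature_names %in% names(features))) {
    abort("feature columns do not match training metadata")
  }
  x <- as.data.frame(features[ensemble$feature_names])
  if (ensemble$global) {
    pred <- predict_forest(ensemble$models$global, x)
  } else {
    nearest <- function(s) {
      if (s %in% ensemble$segments) return(s)
      ensemble$segments[which.min(abs(ensemble$segments - s))]
    }
    s1 <- segment_of(features$bin1, ensemble$segment_bins)
    s2 <- segment_of(features$bin2, ensemble$segment_bins)
    if (!all(unique(c(s1, s2)) %in% ensemble$segments)) {
      warn("some pairs hit segments without a trained model; using nearest trained segment")
      s1 <- vapply(s1, nearest, integer(1))
      s2 <- vapply(s2, nearest, integer(1))
    }
    # predict once per segment model on the rows that touch it
    pred1 <- numeric(nrow(x))
    pred2 <- numeric(nrow(x))
    for (s in unique(c(s1, s2))) {
      m <- ensemble$models[[as.character(s)]]
      rows1 <- which(s1 == s)
      rows2 <- which(s2 == s & s2 != s1)
      rows <- union(rows1, rows2)
      if (length(rows) == 0) next
      p <- predict_forest(m, x[rows, , drop = FALSE])
      names(p) <- rows
      pred1[rows1] <- p[as.character(rows1)]
      pred2[rows2] <- p[as.character(rows2)]
    }
    span <- s1 != s2
    pred <- ifelse(span, (pred1 + pred2) / 2, pred1)
  }
  tibble(chrom = features$chrom, bin1 = features$bin1, bin2 = features$bin2,
         count = pmax(pred, 0))
}

#' Transfer-count baseline
#'
#' Uses the training cell type's measured counts directly as the prediction
#' for the test cell type; pairs absent from the training matrix get 0.
#'
#' @param train_contacts Contact table of the training cell type.
#' @param pairs Tibble (`chrom`, `bin1`, `bin2`) of pairs to predict.
#' @return A contact table of predictions.
#' @export
baseline_transfer_count <- function(train_contacts, pairs) {
  pairs |>
    select("chrom", "bin1", "bin2") |>
    left_join(train_contacts, by = c("chrom", "bin1", "bin2")) |>
    mutate(count = ifelse(is.na(.data$count), 0, .data$count))
}

#' @export
tidy.lhicreg_ensemble <- function(x, ...) {
  if (x$global) {
    m <- x$models$global
    return(tibble(segment = NA_integer_,
                  n_train = if (inherits(m, "constant_model")) NA_integer_ else m$num.samples,
                  oob_mse = if (inherits(m, "constant_model")) NA_real_ else m$prediction.error))
  }
  tibble(
    segment = x$segments,
    n_train = map_int(x$models, function(m) {
      if (inherits(m, "constant_model")) NA_integer_ else as.integer(m$num.samples)
    }),
    oob_mse = map_dbl(x$models, function(m) {
      if (inherits(m, "constant_model")) NA_real_ else m$prediction.error
    }))
}

#' @export
glance.lhicreg_ensemble <- function(x, ...) {
  tibble(n_segments = if (x$global) 1L else length(x$segments),
         trees = x$trees, mtry = x$mtry, global = x$global,
         cell_type = x$cell_type, seed = x$seed)
}

#' @export
print.lhicreg_ensemble <- function(x, ...) {
  kind <- if (x$global) "global single-forest" else
    sprintf("local ensemble (%d segments of %d bins)", length(x$segments),
            x$segment_bins)
  cat(sprintf("<lhicreg_ensemble> %s, %d trees, mtry %d\n", kind, x$trees,
              x$mtry))
  invisible(x)
}
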