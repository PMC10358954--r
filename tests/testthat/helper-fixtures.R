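# Shared fixture builders and small independent oracles used across tests.

# One simulated cell type: contact matrix + matched signal panel.
build_cell_type <- function(seed, noise = 0, seg_sd = 0, n_bins = 400L,
                            n_tads = 6L) {
  spec <- synthetic_spec(n_bins = n_bins, n_tads = n_tads, noise_sd = noise,
                         segment_effect_sd = seg_sd, seed = seed)
  cm <- synth_contact_matrix(spec)
  pan <- synth_signal_panel(spec, cm)
  list(spec = spec, cm = cm, pan = pan)
}

# Feature table for a cell type under given discretization models.
featurize_cell_type <- function(ct, models) {
  levels <- mapply(function(m, tr) apply_discretization(m, tr),
                   models, ct$pan$chip, SIMPLIFY = FALSE)
  add_counts(
    build_pair_features(levels, ct$pan$motif, n_bins = ct$spec$n_bins),
    ct$cm$contacts)
}

fit_panel_models <- function(ct, seed = 1L) {
  lapply(ct$pan$chip, fit_discretization, k = 20L, seed = seed)
}

subsample_rows <- function(df, frac, seed) {
  set.seed(seed)
  df[sort(sample.int(nrow(df), round(frac * nrow(df)))), ]
}

# Independent log-space summation oracle for the upper binomial tail.
binom_tail_oracle <- function(k, n, m) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(m) + (n - i) * log1p(-m)))
}

# Erdos-Renyi adjacency with guaranteed connectivity (re-drawn if needed).
random_connected_adjacency <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p)
    A <- A + t(A)
    dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g)) return(A)
  }
}
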