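# Two-step graph diffusion. Node diffusion spreads the SNP-derived gene
# scores over the network with the regularized Laplacian kernel
# K_L = (I + lambda L)^-1 (L the symmetric normalized Laplacian); edge
# diffusion reweights edges with the insulated heat kernel
# K_H = beta (I - (1-beta) W)^-1 (W = A D^-1 the column transition matrix),
# H = K_H diag(V). The selected submatrix of H is turned into a
# diffusion-state distance matrix (L1 between rows) and a Gaussian
# similarity. All kernels are applied through linear solves, never explicit
# inverses.

# Degree vector with the convention that isolated nodes keep degree 0; their
# D^-1/2 entries are 0 and their transition column is the identity column.
sym_norm_laplacian <- function(A) {
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -(dinv %o% dinv) * A
  diag(L) <- 1
  L
}

transition_matrix <- function(A) {
  d <- colSums(A)
  W <- sweep(A, 2, ifelse(d > 0, d, 1), "/")
  iso <- which(d == 0)
  for (j in iso) W[j, j] <- 1  # isolated node retains its own heat
  W
}

#' Node diffusion with the regularized Laplacian kernel
#'
#' Computes `V = (I + lambda L)^-1 Q` by a linear solve, where L is the
#' symmetric normalized Laplacian of the graph and Q the vector of input
#' node scores.
#'
#' @param graph A `cell_type_graph`, edge tibble, or adjacency matrix.
#' @param scores Named numeric vector of input node scores Q (missing nodes
#'   score 0), or a tibble (`gene_id`, `score`).
#' @param lambda Kernel width (> 0); larger values diffuse farther.
#'   Default 1.
#' @return Named numeric vector V of diffused scores over all graph nodes.
#' @export
node_diffusion <- function(graph, scores, lambda = 1) {
  if (lambda <= 0) abort("lambda must be positive")
  A <- graph_adjacency(graph)
  Q <- score_vector(scores, rownames(A))
  L <- sym_norm_laplacian(A)
  V <- solve(diag(nrow(A)) + lambda * L, Q)
  setNames(as.vector(V), rownames(A))
}

score_vector <- function(scores, nodes) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$gene_id)
  }
  v <- setNames(numeric(length(nodes)), nodes)
  common <- intersect(names(scores), nodes)
  v[common] <- scores[common]
  v
}

#' Select the diffusion kernel width by leave-one-out cross-validation
#'
#' For each lambda in the grid and each direct hit, the hit's score is
#' removed, diffusion is run from the remaining hits, and the held-out
#' gene's diffused score is ranked against all non-hit genes. AUROC is the
#' mean over folds of the fraction of non-hit genes scored below the
#' held-out hit (ties count one half). Ties in AUROC resolve to the smaller
#' lambda.
#'
#' @param graph Graph as in [node_diffusion()].
#' @param scores Input node scores; nonzero entries define the direct hits.
#' @param grid Candidate lambda values (default {0.1, 0.5, 1, 5, 10}).
#' @return A list: `lambda` (selected), `auroc` (tibble lambda/auroc).
#' @export
select_lambda_loocv <- function(graph, scores, grid = c(0.1, 0.5, 1, 5, 10)) {
  A <- graph_adjacency(graph)
  Q <- score_vector(scores, rownames(A))
  hits <- names(Q)[Q > 0]
  if (length(hits) < 3) abort("need at least 3 direct hits for LOO-CV")
  nonhits <- setdiff(rownames(A), hits)
  L <- sym_norm_laplacian(A)
  I <- diag(nrow(A))
  res <- map(grid, function(lam) {
    # one factorization per lambda, all folds solved together
    Qs <- vapply(hits, function(h) {
      q <- Q; q[h] <- 0; q
    }, numeric(length(Q)))
    Vs <- solve(I + lam * L, Qs)
    rownames(Vs) <- rownames(A)
    fold_auc <- vapply(seq_along(hits), function(f) {
      v <- Vs[, f]
      held <- v[hits[f]]
      neg <- v[nonhits]
      (sum(neg < held) + 0.5 * sum(neg == held)) / length(neg)
    }, numeric(1))
    tibble(lambda = lam, auroc = mean(fold_auc))
  }) |>
    list_rbind()
  best <- res |>
    filter(.data$auroc == max(.data$auroc)) |>
    slice_min(.data$lambda, n = 1)
  list(lambda = best$lambda[[1]], auroc = res)
}

#' Edge diffusion with the insulated heat kernel
#'
#' Computes `K_H = beta (I - (1 - beta) W)^-1` by a linear solve and the
#' reweighted adjacency `H = K_H diag(V)`.
#'
#' @param graph Graph as in [node_diffusion()].
#' @param V Named vector of node-diffused scores (from [node_diffusion()]).
#' @param beta Retention rate in (0, 1]; default 0.3.
#' @return A list: `K_H` and `H` (both node x node matrices).
#' @export
edge_diffusion <- function(graph, V, beta = 0.3) {
  if (beta <= 0 || beta > 1) abort("beta must lie in (0, 1]")
  A <- graph_adjacency(graph)
  W <- transition_matrix(A)
  K_H <- beta * solve(diag(nrow(A)) - (1 - beta) * W)
  dimnames(K_H) <- dimnames(A)
  H <- K_H %*% diag(score_vector(V, rownames(A)))
  dimnames(H) <- dimnames(A)
  list(K_H = K_H, H = H)
}

#' Node selection, diffusion-state distance, and Gaussian similarity
#'
#' Selects the direct hits plus the top fraction of diffused node scores
#' (ties at the cutoff included), restricts H to the selected rows and
#' columns, and converts it into the DSD matrix `P[i, j] = ||u_i - u_j||_1`
#' over the restricted rows, then into the similarity
#' `S = exp(-P^2 / (2 sigma_P^2))` with sigma_P the population standard
#' deviation of all entries of P.
#'
#' @param H Edge-diffused matrix from [edge_diffusion()].
#' @param V Named vector of diffused node scores.
#' @param direct_hits Character vector of direct-hit gene ids.
#' @param top_frac Fraction of top diffused scores to add (default 0.01).
#' @return A list: `selected`, `P`, `sigma`, `S`.
#' @export
select_nodes_and_dsd <- function(H, V, direct_hits, top_frac = 0.01) {
  nodes <- rownames(H)
  V <- score_vector(V, nodes)
  n_top <- ceiling(top_frac * length(nodes))
  cutoff <- sort(V, decreasing = TRUE)[n_top]
  top <- names(V)[V >= cutoff]
  selected <- nodes[nodes %in% union(direct_hits, top)]
  if (length(selected) < 3) abort("fewer than 3 selected nodes")
  Hr <- H[selected, selected, drop = FALSE]
  P <- as.matrix(dist(Hr, method = "manhattan"))
  sigma <- sqrt(mean((P - mean(P))^2))  # population SD of all entries
  S <- if (sigma > 0) exp(-P^2 / (2 * sigma^2)) else matrix(1, nrow(P), ncol(P))
  dimnames(S) <- dimnames(P)
  list(selected = selected, P = P, sigma = sigma, S = S)
}

#' Run the full two-step diffusion for one cell type
#'
#' [node_diffusion()], then [edge_diffusion()], then
#' [select_nodes_and_dsd()], bundled with tidy/glance/autoplot methods.
#'
#' @inheritParams node_diffusion
#' @inheritParams edge_diffusion
#' @inheritParams select_nodes_and_dsd
#' @param skip_node_diffusion Use the raw input scores for `D_V` instead of
#'   node-diffused scores (the one-step alternative; for comparison).
#' @return Object of class `diffusion_result`: list with `Q`, `V`, `H`,
#'   `selected`, `P`, `sigma`, `S`, `lambda`, `beta`.
#' @export
diffuse_network <- function(graph, scores, lambda = 1, beta = 0.3,
                            top_frac = 0.01, skip_node_diffusion = FALSE) {
  A <- graph_adjacency(graph)
  Q <- score_vector(scores, rownames(A))
  V <- if (skip_node_diffusion) Q else node_diffusion(A, Q, lambda)
  ed <- edge_diffusion(A, V, beta)
  hits <- names(Q)[Q > 0]
  sel <- select_nodes_and_dsd(ed$H, V, hits, top_frac)
  structure(list(Q = Q, V = V, H = ed$H, selected = sel$selected, P = sel$P,
                 sigma = sel$sigma, S = sel$S, lambda = lambda, beta = beta,
                 direct_hits = hits),
            class = "diffusion_result")
}

#' @export
tidy.diffusion_result <- function(x, ...) {
  tibble(gene_id = names(x$V), input_score = as.vector(x$Q),
         diffused_score = as.vector(x$V),
         direct_hit = names(x$V) %in% x$direct_hits,
         selected = names(x$V) %in% x$selected)
}

#' @export
glance.diffusion_result <- function(x, ...) {
  tibble(lambda = x$lambda, beta = x$beta, n_nodes = length(x$V),
         n_direct_hits = length(x$direct_hits),
         n_selected = length(x$selected), sigma_P = x$sigma)
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf(
    "<diffusion_result> %d nodes, %d direct hits, %d selected (lambda=%g, beta=%g)\n",
    length(x$V), length(x$direct_hits), length(x$selected), x$lambda, x$beta))
  invisible(x)
}

#' @export
autoplot.diffusion_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$diffused_score, fill = .data$direct_hit)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::scale_x_log10() +
    labs(x = "diffused node score", y = "genes") +
    theme_minimal()
}
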