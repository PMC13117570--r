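#' Structural (topology) features for every node
#'
#' The standard centrality battery, computed once on the full graph (all
#' metrics are label-free, so no fold leakage), in this fixed column order:
#' degree, normalized betweenness, closeness (per-component convention),
#' eigenvector centrality, local clustering coefficient, PageRank
#' (damping 0.85), and core number. Isolated nodes get 0 where a metric is
#' undefined.
#'
#' @param graph a [gene_graph()].
#' @return list with `values` (N x 7 matrix) and `metric_names`.
#' @export
structural_features <- function(graph) {
  g <- igraph_from_gene_graph(graph)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- if (n > 2) igraph::betweenness(g, normalized = TRUE) else rep(0, n)
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  eig <- if (igraph::ecount(g) > 0) {
    igraph::eigen_centrality(g)$vector
  } else {
    rep(0, n)
  }
  clu <- igraph::transitivity(g, type = "local", isolates = "zero")
  pr <- igraph::page_rank(g, damping = 0.85)$vector
  core <- igraph::coreness(g)
  vals <- cbind(degree = deg, betweenness = btw, closeness = cls,
                eigenvector = eig, clustering = clu, pagerank = pr,
                core = core)
  rownames(vals) <- graph$symbols
  list(values = unname(vals), metric_names = colnames(vals))
}

igraph_from_gene_graph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges, directed = FALSE) |>
    (\(g) {
      miss <- length(graph$symbols) - igraph::vcount(g)
      if (miss > 0) igraph::add_vertices(g, miss) else g
    })()
}

#' Biased second-order random walks
#'
#' node2vec-style walks with return parameter `p` and in-out parameter `q`:
#' stepping from v (arrived from t), the unnormalized probability of moving
#' to neighbor x is 1/p if x = t, 1 if x is adjacent to t, and 1/q
#' otherwise. Isolated nodes yield length-1 walks.
#'
#' @param graph a [gene_graph()].
#' @param p,q bias parameters (> 0).
#' @param walk_length steps per walk.
#' @param walks_per_node walks started at every node.
#' @param seed optional RNG seed.
#' @return integer matrix, one walk per row, 1-based node indices, `NA`
#'   padding after early termination.
#' @export
node2vec_walks <- function(graph, p = 1, q = 1, walk_length = 80L,
                           walks_per_node = 10L, seed = NULL) {
  stopifnot(p > 0, q > 0, walk_length >= 1, walks_per_node >= 1)
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency_list0(graph)
  w <- cpp_node2vec_walks(adj, p, q, as.integer(walk_length),
                          as.integer(walks_per_node))
  w[w < 0L] <- NA_integer_
  w + 1L
}

# 0-based sorted adjacency list for the C++ walker
adjacency_list0 <- function(graph) {
  n <- length(graph$symbols)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  e <- graph$edges
  if (nrow(e) > 0) {
    tmp <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
    for (k in names(tmp)) adj[[as.integer(k)]] <- sort(unique(tmp[[k]]))
  }
  lapply(adj, function(v) as.integer(v - 1L))
}

#' Skip-gram node embeddings from biased walks
#'
#' Generates a walk corpus with [node2vec_walks()] and trains a skip-gram
#' model with negative sampling (unigram^0.75 noise distribution, linearly
#' decaying learning rate) over it. Deterministic given `seed`.
#'
#' @inheritParams node2vec_walks
#' @param dim embedding width.
#' @param window skip-gram context window.
#' @param epochs passes over the corpus.
#' @param n_negative negative samples per positive pair.
#' @param lr initial learning rate.
#' @return list with `values` (N x dim matrix) and `walk_params`.
#' @export
node2vec_embed <- function(graph, p = 1, q = 1, walk_length = 80L,
                           walks_per_node = 10L, window = 10L, dim = 32L,
                           epochs = 2L, n_negative = 5L, lr = 0.025,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  walks <- node2vec_walks(graph, p, q, walk_length, walks_per_node)
  w0 <- walks - 1L
  w0[is.na(w0)] <- -1L
  emb <- cpp_skipgram_train(w0, length(graph$symbols), as.integer(dim),
                            as.integer(window), as.integer(n_negative),
                            lr, as.integer(epochs))
  rownames(emb) <- graph$symbols
  list(values = unname(emb),
       walk_params = list(p = p, q = q, walk_length = walk_length,
                          walks_per_node = walks_per_node, window = window,
                          dim = dim, seed = seed))
}

#' Assemble the feature-enhancement input block
#'
#' Concatenates the active extra-feature sources (structural metrics, walk
#' embeddings, teacher soft-label logits) column-wise into `X_extra`.
#'
#' @param structural `values` matrix from [structural_features()] or NULL.
#' @param walks `values` matrix from [node2vec_embed()] or NULL.
#' @param teacher_logits N x 1 matrix of teacher soft labels or NULL.
#' @param use_structural,use_walks,use_teacher source toggles.
#' @return N x (7 + d_w + 1) matrix (active sources only), or NULL when all
#'   toggles are off.
#' @export
enhancement_bundle <- function(structural = NULL, walks = NULL,
                               teacher_logits = NULL,
                               use_structural = TRUE, use_walks = TRUE,
                               use_teacher = TRUE) {
  parts <- list()
  if (use_structural) {
    if (is.null(structural)) stop("structural features requested but missing")
    parts <- c(parts, list(as.matrix(structural)))
  }
  if (use_walks) {
    if (is.null(walks)) stop("walk embeddings requested but missing")
    parts <- c(parts, list(as.matrix(walks)))
  }
  if (use_teacher) {
    if (is.null(teacher_logits)) stop("teacher logits requested but missing")
    parts <- c(parts, list(matrix(as.numeric(teacher_logits), ncol = 1L)))
  }
  if (length(parts) == 0L) return(NULL)
  ns <- unique(vapply(parts, nrow, integer(1)))
  if (length(ns) != 1L) stop("enhancement sources disagree on node count")
  do.call(cbind, parts)
}

init_enhance_mlp <- function(d_extra, d_h) {
  init_mlp(c(d_extra, d_h, d_h))
}

#' Residual feature enhancement
#'
#' `H_enhanced = H_fused + MLP_extra(X_extra)`; with `X_extra = NULL`
#' (all sources toggled off) this is the identity on `H_fused`.
#'
#' @param H_fused N x d_h fused representation.
#' @param X_extra enhancement block from [enhancement_bundle()] or NULL.
#' @param params MLP parameters (`W1`, `b1`, `W2`, `b2`); defaults to a
#'   fresh initialization.
#' @return N x d_h matrix.
#' @export
enhance <- function(H_fused, X_extra, params = NULL) {
  H_fused <- as.matrix(H_fused)
  if (is.null(X_extra)) return(H_fused)
  X_extra <- as.matrix(X_extra)
  if (is.null(params)) params <- init_enhance_mlp(ncol(X_extra), ncol(H_fused))
  tape <- ad_tape()
  ctx <- fwd_ctx(flatten_params(list(mx = params)), tape)
  extra <- mlp_forward(ctx, "mx", X_extra, 2L)
  H_fused + extra$value
}
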