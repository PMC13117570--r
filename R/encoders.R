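#' @useDynLib drivergnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# -- parameter initialization -------------------------------------------------

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

zeros_row <- function(d) matrix(0, 1L, d)
ones_row <- function(d) matrix(1, 1L, d)

# residual GCN layer: linear path and convolution path, no biases (the
# merge in the layer rule is purely additive)
init_residual_layer <- function(d_in, d_out) {
  list(WL = glorot(d_in, d_out), Wc = glorot(d_in, d_out))
}

# a two-layer residual-GCN omics encoder with a final layer norm
init_encoder <- function(d_in, h1, h2) {
  list(l1 = init_residual_layer(d_in, h1),
       l2 = init_residual_layer(h1, h2),
       ln_gamma = ones_row(h2), ln_beta = zeros_row(h2))
}

init_mlp <- function(widths) {
  # widths = c(d_in, hidden..., d_out); ReLU between layers, linear last
  out <- list()
  for (i in seq_len(length(widths) - 1L)) {
    out[[paste0("W", i)]] <- glorot(widths[i], widths[i + 1L])
    out[[paste0("b", i)]] <- zeros_row(widths[i + 1L])
  }
  out
}

# flatten a nested list of matrices into "a.b.c" named entries
flatten_params <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

# fetch the tape leaf for params[[name]], creating it on first use
pget <- function(ctx, name) {
  if (is.null(ctx$leaves[[name]])) {
    if (is.null(ctx$params[[name]])) stop("unknown parameter: ", name)
    ctx$leaves[[name]] <- ad_param(ctx$tape, ctx$params[[name]], name)
  }
  ctx$leaves[[name]]
}

# forward context: tape + parameter store + created leaves
fwd_ctx <- function(params, tape) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$tape <- tape
  ctx$leaves <- list()
  ctx
}

# -- residual GCN layers ------------------------------------------------------

#' Residual GCN layer forward pass
#'
#' Computes \eqn{\sigma(H W_L) + \sigma(\hat A_{norm} H W_c)} with
#' \eqn{\sigma} = ReLU: a node-wise linear path and a neighborhood
#' convolution path merged additively, which keeps gradients flowing in
#' deep stacks.
#'
#' @param ctx forward context from `fwd_ctx`.
#' @param prefix parameter-name prefix holding `WL`, `Wc`.
#' @param H input node (N x d_in).
#' @param adnorm normalized adjacency node (constant sparse operator).
#' @keywords internal
residual_gcn_layer <- function(ctx, prefix, H, adnorm) {
  lin <- ad_relu(ad_matmul(H, pget(ctx, paste0(prefix, ".WL")), ctx$tape),
                 ctx$tape)
  conv <- ad_relu(ad_matmul(ad_spmm(adnorm, H, ctx$tape),
                            pget(ctx, paste0(prefix, ".Wc")), ctx$tape),
                  ctx$tape)
  ad_add(lin, conv, ctx$tape)
}

# two residual layers + layer norm; `adnorm` is the plain sparse operator
encoder_forward <- function(ctx, prefix, X, adnorm) {
  Xn <- if (is.environment(X)) X else ad_const(ctx$tape, X)
  h <- residual_gcn_layer(ctx, paste0(prefix, ".l1"), Xn, adnorm)
  h <- residual_gcn_layer(ctx, paste0(prefix, ".l2"), h, adnorm)
  ad_layernorm(h, pget(ctx, paste0(prefix, ".ln_gamma")),
               pget(ctx, paste0(prefix, ".ln_beta")), ctx$tape)
}

mlp_forward <- function(ctx, prefix, X, n_layers, final_linear = TRUE) {
  h <- if (is.environment(X)) X else ad_const(ctx$tape, X)
  for (i in seq_len(n_layers)) {
    h <- ad_add_bias(ad_matmul(h, pget(ctx, paste0(prefix, ".W", i)), ctx$tape),
                     pget(ctx, paste0(prefix, ".b", i)), ctx$tape)
    if (i < n_layers || !final_linear) h <- ad_relu(h, ctx$tape)
  }
  h
}

# -- alternative encoders (ablation variants) ---------------------------------

# GraphSAGE-style shared encoder: h = ReLU(X W_self + meanA X W_neigh),
# mean aggregation over neighbors (row-normalized adjacency, no self loop)
init_sage_encoder <- function(d_in, h1, h2) {
  list(l1 = list(Wself = glorot(d_in, h1), Wneigh = glorot(d_in, h1),
                 b = zeros_row(h1)),
       l2 = list(Wself = glorot(h1, h2), Wneigh = glorot(h1, h2),
                 b = zeros_row(h2)),
       ln_gamma = ones_row(h2), ln_beta = zeros_row(h2))
}

sage_layer <- function(ctx, prefix, H, mean_adj) {
  s <- ad_matmul(H, pget(ctx, paste0(prefix, ".Wself")), ctx$tape)
  nb <- ad_matmul(ad_spmm(mean_adj, H, ctx$tape),
                  pget(ctx, paste0(prefix, ".Wneigh")), ctx$tape)
  ad_relu(ad_add_bias(ad_add(s, nb, ctx$tape),
                      pget(ctx, paste0(prefix, ".b")), ctx$tape), ctx$tape)
}

sage_forward <- function(ctx, prefix, X, mean_adj) {
  Xn <- if (is.environment(X)) X else ad_const(ctx$tape, X)
  h <- sage_layer(ctx, paste0(prefix, ".l1"), Xn, mean_adj)
  h <- sage_layer(ctx, paste0(prefix, ".l2"), h, mean_adj)
  ad_layernorm(h, pget(ctx, paste0(prefix, ".ln_gamma")),
               pget(ctx, paste0(prefix, ".ln_beta")), ctx$tape)
}

# row-normalized adjacency for mean aggregation; isolated rows stay zero
mean_adjacency <- function(A) {
  d <- Matrix::rowSums(A)
  d[d == 0] <- 1
  methods::as(Matrix::Diagonal(nrow(A), 1 / d) %*% A, "generalMatrix")
}

# single-head graph attention (GAT) layer, dense masked softmax over the
# closed neighborhood; adequate for the desk-scale graphs the ablation runs on
init_gat_encoder <- function(d_in, h1, h2) {
  list(l1 = list(W = glorot(d_in, h1), a_src = glorot(h1, 1L),
                 a_dst = glorot(h1, 1L)),
       l2 = list(W = glorot(h1, h2), a_src = glorot(h2, 1L),
                 a_dst = glorot(h2, 1L)),
       ln_gamma = ones_row(h2), ln_beta = zeros_row(h2))
}

gat_layer <- function(ctx, prefix, H, mask) {
  Z <- ad_matmul(H, pget(ctx, paste0(prefix, ".W")), ctx$tape)
  s <- ad_matmul(Z, pget(ctx, paste0(prefix, ".a_src")), ctx$tape)
  d <- ad_matmul(Z, pget(ctx, paste0(prefix, ".a_dst")), ctx$tape)
  E <- ad_leakyrelu(ad_outer_sum(s, d, ctx$tape), ctx$tape)
  att <- ad_masked_softmax_rows(E, mask, ctx$tape)
  ad_relu(ad_matmul(att, Z, ctx$tape), ctx$tape)
}

gat_forward <- function(ctx, prefix, X, mask) {
  Xn <- if (is.environment(X)) X else ad_const(ctx$tape, X)
  h <- gat_layer(ctx, paste0(prefix, ".l1"), Xn, mask)
  h <- gat_layer(ctx, paste0(prefix, ".l2"), h, mask)
  ad_layernorm(h, pget(ctx, paste0(prefix, ".ln_gamma")),
               pget(ctx, paste0(prefix, ".ln_beta")), ctx$tape)
}

# -- training-time augmentation ----------------------------------------------

#' Random feature-mask and edge-drop augmentation
#'
#' Zeroes each feature entry independently with probability
#' `feature_mask_rate` and removes each undirected edge (both directions
#' together) with probability `edge_drop_rate`, then recomputes the
#' symmetric normalization on the perturbed graph. Draws from R's RNG, so
#' reproducibility follows from `set.seed()` upstream (or pass `seed`).
#'
#' @param X numeric feature matrix (already standardized).
#' @param graph a [gene_graph()].
#' @param feature_mask_rate,edge_drop_rate probabilities in `[0, 1)`.
#' @param seed optional integer; if given, seeds the RNG first.
#' @return list with `X` (masked copy), `norm_adjacency` (recomputed
#'   operator), and `n_edges` surviving.
#' @export
augment <- function(X, graph, feature_mask_rate = 0.1, edge_drop_rate = 0.1,
                    seed = NULL) {
  if (feature_mask_rate < 0 || feature_mask_rate >= 1 ||
      edge_drop_rate < 0 || edge_drop_rate >= 1) {
    stop("augmentation rates must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  Xp <- X
  if (feature_mask_rate > 0) {
    Xp <- Xp * (matrix(stats::runif(length(X)), nrow(X)) >= feature_mask_rate)
  }
  e <- graph$edges
  if (edge_drop_rate > 0 && nrow(e) > 0) {
    keep <- stats::runif(nrow(e)) >= edge_drop_rate
    e <- e[keep, , drop = FALSE]
  }
  n <- length(graph$symbols)
  A <- if (nrow(e) > 0) {
    Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                         x = 1, dims = c(n, n))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  }
  list(X = Xp, norm_adjacency = normalize_operator(A), n_edges = nrow(e))
}
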