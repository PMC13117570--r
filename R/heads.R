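# Dual prediction heads: a projection layer (residual GCN, width 128), a
# deep 6-layer residual GCN classifier (width 200, dropout after each
# additive merge), a 3-layer MLP classifier with input layer normalization,
# and additive logit fusion y = y_G + y_m.

init_heads <- function(d_h, proj_dim = 128L, gcn_width = 200L,
                       gcn_depth = 6L, mlp_widths = c(256L, 128L, 64L)) {
  gcn <- list()
  din <- proj_dim
  for (l in seq_len(gcn_depth)) {
    gcn[[paste0("l", l)]] <- init_residual_layer(din, gcn_width)
    din <- gcn_width
  }
  gcn$out_W <- glorot(gcn_width, 1L)
  gcn$out_b <- zeros_row(1L)
  mlp <- init_mlp(c(proj_dim, mlp_widths))
  mlp$ln_gamma <- ones_row(proj_dim)
  mlp$ln_beta <- zeros_row(proj_dim)
  mlp$out_W <- glorot(mlp_widths[length(mlp_widths)], 1L)
  mlp$out_b <- zeros_row(1L)
  list(proj = init_residual_layer(d_h, proj_dim), gcn = gcn, mlp = mlp)
}

# GCN classifier head: per layer ReLU linear + ReLU convolution paths merged
# additively, dropout after the merge; linear output layer
gcn_head_forward <- function(ctx, prefix, H, adnorm, depth, dropout,
                             training) {
  h <- H
  for (l in seq_len(depth)) {
    h <- residual_gcn_layer(ctx, paste0(prefix, ".l", l), h, adnorm)
    h <- ad_dropout(h, dropout, training, ctx$tape)
  }
  ad_add_bias(ad_matmul(h, pget(ctx, paste0(prefix, ".out_W")), ctx$tape),
              pget(ctx, paste0(prefix, ".out_b")), ctx$tape)
}

# MLP head: LayerNorm on the projected input, then ReLU/ReLU/linear layers
# with dropout on the third, and a linear output layer
mlp_head_forward <- function(ctx, prefix, H, dropout, training) {
  h <- ad_layernorm(H, pget(ctx, paste0(prefix, ".ln_gamma")),
                    pget(ctx, paste0(prefix, ".ln_beta")), ctx$tape)
  h <- ad_relu(ad_add_bias(ad_matmul(h, pget(ctx, paste0(prefix, ".W1")),
                                     ctx$tape),
                           pget(ctx, paste0(prefix, ".b1")), ctx$tape),
               ctx$tape)
  h <- ad_relu(ad_add_bias(ad_matmul(h, pget(ctx, paste0(prefix, ".W2")),
                                     ctx$tape),
                           pget(ctx, paste0(prefix, ".b2")), ctx$tape),
               ctx$tape)
  h <- ad_add_bias(ad_matmul(h, pget(ctx, paste0(prefix, ".W3")), ctx$tape),
                   pget(ctx, paste0(prefix, ".b3")), ctx$tape)
  h <- ad_dropout(h, dropout, training, ctx$tape)
  ad_add_bias(ad_matmul(h, pget(ctx, paste0(prefix, ".out_W")), ctx$tape),
              pget(ctx, paste0(prefix, ".out_b")), ctx$tape)
}

heads_forward <- function(ctx, H_enh, adnorm, config, training) {
  proj <- residual_gcn_layer(ctx, "heads.proj", H_enh, adnorm)
  yG <- gcn_head_forward(ctx, "heads.gcn", proj, adnorm,
                         config$gcn_head_depth, config$dropout, training)
  if (identical(config$head, "gcn_only")) {
    return(list(logits = yG, yG = yG, ym = NULL))
  }
  ym <- mlp_head_forward(ctx, "heads.mlp", proj, config$dropout, training)
  list(logits = ad_add(yG, ym, ctx$tape), yG = yG, ym = ym)
}

#' Dual-head forward pass on a fixed representation
#'
#' Projects an enhanced node representation to 128 dimensions with a
#' residual GCN layer, runs the 6-layer GCN classifier head and the 3-layer
#' MLP head in parallel, and sums their logits. Dropout is active only when
#' `eval_mode = FALSE`.
#'
#' @param H_enhanced N x d_h numeric matrix.
#' @param norm_adj sparse normalized adjacency operator.
#' @param params head parameters from the model (or NULL for a fresh random
#'   initialization via `init_heads`).
#' @param config a [model_config()]; only the head fields are used.
#' @param eval_mode disable dropout (default TRUE).
#' @return list with `logits`, `probabilities`, `head_logits` (list of
#'   `yG`, `ym`).
#' @export
forward_heads <- function(H_enhanced, norm_adj, params = NULL,
                          config = model_config(), eval_mode = TRUE) {
  H_enhanced <- as.matrix(H_enhanced)
  if (is.null(params)) {
    params <- init_heads(ncol(H_enhanced), config$proj_dim,
                         config$gcn_head_width, config$gcn_head_depth,
                         config$mlp_head_widths)
  }
  tape <- ad_tape()
  ctx <- fwd_ctx(flatten_params(list(heads = params)), tape)
  out <- heads_forward(ctx, ad_const(tape, H_enhanced), norm_adj, config,
                       training = !eval_mode)
  logits <- as.numeric(out$logits$value)
  list(logits = logits,
       probabilities = sigmoid_probability(logits),
       head_logits = list(yG = as.numeric(out$yG$value),
                          ym = if (is.null(out$ym)) NULL
                               else as.numeric(out$ym$value)))
}

#' Convert logits to probabilities
#'
#' Elementwise logistic sigmoid `1 / (1 + exp(-x))`, numerically stable for
#' large |x|.
#'
#' @param logits numeric vector or matrix.
#' @return probabilities in (0, 1), same shape.
#' @export
sigmoid_probability <- function(logits) {
  stats::plogis(logits)
}
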