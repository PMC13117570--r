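# Per-node additive attention over the four omics embeddings.
#
# For node i and omics m the score is v' sigma(W_a s_i^(m) + b_a); a softmax
# across the four omics turns scores into per-node weights, and the fused
# representation is the weight-scaled sum of the omics rows.

init_attention <- function(d_h, d_a) {
  list(Wa = glorot(d_h, d_a), ba = zeros_row(d_a), v = glorot(d_a, 1L))
}

attention_forward <- function(ctx, prefix, Hs, sigma = c("tanh", "relu")) {
  sigma <- match.arg(sigma)
  act <- if (sigma == "tanh") ad_tanh else ad_relu
  scores <- lapply(Hs, function(H) {
    z <- ad_add_bias(ad_matmul(H, pget(ctx, paste0(prefix, ".Wa")), ctx$tape),
                     pget(ctx, paste0(prefix, ".ba")), ctx$tape)
    ad_matmul(act(z, ctx$tape), pget(ctx, paste0(prefix, ".v")), ctx$tape)
  })
  S <- ad_concat_cols(scores, ctx$tape)
  W <- ad_softmax_rows(S, ctx$tape)
  fused <- NULL
  for (m in seq_along(Hs)) {
    term <- ad_scale_rows(Hs[[m]], ad_col(W, m, ctx$tape), ctx$tape)
    fused <- if (is.null(fused)) term else ad_add(fused, term, ctx$tape)
  }
  list(fused = fused, weights = W$value)
}

#' Attention fusion of four omics embeddings
#'
#' Scores each omics embedding per node with an additive attention network
#' (`score = v' sigma(W_a s + b_a)`), softmaxes the four scores into
#' per-node weights, and returns the weighted elementwise sum.
#'
#' @param Hs list of four N x d_h numeric matrices (mutation, expression,
#'   methylation, CNV embeddings).
#' @param params list with `Wa` (d_h x d_a), `ba` (1 x d_a), `v` (d_a x 1);
#'   defaults to a fresh random initialization with `d_a = 64`.
#' @param sigma activation inside the attention network.
#' @return list with `values` (N x d_h fused matrix) and
#'   `attention_weights` (N x 4, rows summing to 1).
#' @export
attend <- function(Hs, params = NULL, sigma = c("tanh", "relu")) {
  sigma <- match.arg(sigma)
  stopifnot(length(Hs) == 4L)
  dims <- vapply(Hs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("the four embeddings must share a shape")
  if (is.null(params)) params <- init_attention(ncol(Hs[[1L]]), 64L)
  tape <- ad_tape()
  ctx <- fwd_ctx(flatten_params(list(att = params)), tape)
  Hn <- lapply(Hs, function(H) ad_const(tape, as.matrix(H)))
  out <- attention_forward(ctx, "att", Hn, sigma)
  list(values = out$fused$value, attention_weights = out$weights)
}

#' Sum fusion of the four omics embeddings (ablation)
#'
#' The "without attention layer" variant: a plain elementwise sum. The
#' reported weights are a constant 1 (unnormalized by design; this is the
#' ablation's semantics, not a probability).
#'
#' @inheritParams attend
#' @return list with `values` and `attention_weights` (all ones).
#' @export
fuse_without_attention <- function(Hs) {
  stopifnot(length(Hs) == 4L)
  list(values = Reduce(`+`, lapply(Hs, as.matrix)),
       attention_weights = matrix(1, nrow(Hs[[1L]]), 4L))
}
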