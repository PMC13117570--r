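#' Reverse-mode automatic differentiation tape
#'
#' A minimal dynamic computation graph for dense-matrix neural networks with
#' constant sparse graph operators. Every operation appends a node to the
#' tape; [ad_backward()] walks the tape in reverse creation order and
#' accumulates gradients into parameter leaves. The engine supports exactly
#' the operations the model needs (matrix product, sparse propagation,
#' bias/elementwise arithmetic, ReLU, tanh, row layer-normalization, row
#' softmax, column concatenation, row scaling, inverted dropout) and is not
#' a general tensor library.
#'
#' @return An environment holding the tape (`nodes`, `n`).
#' @keywords internal
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    param_name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param_name <- param_name
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

#' @keywords internal
ad_const <- function(tape, value) ad_node(tape, value)

#' Parameter leaf: gradient is collected under `name` after backward.
#' @keywords internal
ad_param <- function(tape, value, name) {
  ad_node(tape, value, param_name = name)
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Dense matrix product X %*% W.
#' @keywords internal
ad_matmul <- function(x, w, tape) {
  ad_node(tape, x$value %*% w$value, parents = list(x, w),
          backward = function(nd) {
            g <- nd$grad
            ad_accum(nd$parents[[1]], tcrossprod(g, nd$parents[[2]]$value))
            ad_accum(nd$parents[[2]], crossprod(nd$parents[[1]]$value, g))
          })
}

#' Sparse propagation A %*% X with A a constant symmetric operator.
#' @keywords internal
ad_spmm <- function(a, x, tape) {
  force(a)
  ad_node(tape, as.matrix(a %*% x$value), parents = list(x),
          backward = function(nd) {
            # A symmetric: d/dX = A^T G = A G
            ad_accum(nd$parents[[1]], as.matrix(a %*% nd$grad))
          })
}

#' @keywords internal
ad_add <- function(x, y, tape) {
  ad_node(tape, x$value + y$value, parents = list(x, y),
          backward = function(nd) {
            ad_accum(nd$parents[[1]], nd$grad)
            ad_accum(nd$parents[[2]], nd$grad)
          })
}

#' Add a length-d bias row vector to every row of an N x d matrix.
#' @keywords internal
ad_add_bias <- function(x, b, tape) {
  bv <- as.numeric(b$value)
  ad_node(tape, x$value + rep(bv, each = nrow(x$value)), parents = list(x, b),
          backward = function(nd) {
            ad_accum(nd$parents[[1]], nd$grad)
            gb <- colSums(nd$grad)
            dim(gb) <- dim(nd$parents[[2]]$value)
            ad_accum(nd$parents[[2]], gb)
          })
}

#' @keywords internal
ad_relu <- function(x, tape) {
  mask <- x$value > 0
  ad_node(tape, x$value * mask, parents = list(x),
          backward = function(nd) ad_accum(nd$parents[[1]], nd$grad * mask))
}

#' @keywords internal
ad_tanh <- function(x, tape) {
  v <- tanh(x$value)
  ad_node(tape, v, parents = list(x),
          backward = function(nd) ad_accum(nd$parents[[1]], nd$grad * (1 - v^2)))
}

#' Row-wise layer normalization with learnable gain and bias.
#'
#' For each row x: (x - mean(x)) / sqrt(var(x) + eps) * gamma + beta, with
#' the population variance over the feature dimension.
#' @keywords internal
ad_layernorm <- function(x, gamma, beta, tape, eps = 1e-5) {
  X <- x$value
  d <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  n <- nrow(X)
  out <- xhat * rep(gv, each = n) + rep(bv, each = n)
  ad_node(tape, out, parents = list(x, gamma, beta),
          backward = function(nd) {
            G <- nd$grad
            gg <- colSums(G * xhat)
            dim(gg) <- dim(nd$parents[[2]]$value)
            ad_accum(nd$parents[[2]], gg)
            gb <- colSums(G)
            dim(gb) <- dim(nd$parents[[3]]$value)
            ad_accum(nd$parents[[3]], gb)
            dxhat <- G * rep(gv, each = nrow(G))
            # standard layer-norm backward, per row
            dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
            ad_accum(nd$parents[[1]], dx)
          })
}

#' Row softmax over the columns of an N x k matrix.
#' @keywords internal
ad_softmax_rows <- function(x, tape) {
  X <- x$value
  m <- apply(X, 1L, max)
  e <- exp(X - m)
  p <- e / rowSums(e)
  ad_node(tape, p, parents = list(x),
          backward = function(nd) {
            G <- nd$grad
            ad_accum(nd$parents[[1]], p * (G - rowSums(G * p)))
          })
}

#' Column-wise concatenation of a list of N x d_i matrices.
#' @keywords internal
ad_concat_cols <- function(xs, tape) {
  widths <- vapply(xs, function(x) ncol(x$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(xs, function(x) x$value)), parents = xs,
          backward = function(nd) {
            for (i in seq_along(nd$parents)) {
              ad_accum(nd$parents[[i]],
                       nd$grad[, starts[i]:ends[i], drop = FALSE])
            }
          })
}

#' Scale each row of X (N x d) by the matching entry of s (N x 1).
#' @keywords internal
ad_scale_rows <- function(x, s, tape) {
  sv <- as.numeric(s$value)
  ad_node(tape, x$value * sv, parents = list(x, s),
          backward = function(nd) {
            G <- nd$grad
            ad_accum(nd$parents[[1]], G * sv)
            gs <- rowSums(G * nd$parents[[1]]$value)
            dim(gs) <- c(length(gs), 1L)
            ad_accum(nd$parents[[2]], gs)
          })
}

#' Select one column of an N x k matrix as an N x 1 node.
#' @keywords internal
ad_col <- function(x, j, tape) {
  ad_node(tape, x$value[, j, drop = FALSE], parents = list(x),
          backward = function(nd) {
            G <- matrix(0, nrow(nd$parents[[1]]$value), ncol(nd$parents[[1]]$value))
            G[, j] <- nd$grad
            ad_accum(nd$parents[[1]], G)
          })
}

#' Inverted dropout: training-time only; draws its mask from R's RNG.
#' @keywords internal
ad_dropout <- function(x, rate, training, tape) {
  if (!training || rate <= 0) return(x)
  keep <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= rate) / (1 - rate)
  ad_node(tape, x$value * keep, parents = list(x),
          backward = function(nd) ad_accum(nd$parents[[1]], nd$grad * keep))
}

#' Elementwise product with a constant mask matrix.
#' @keywords internal
ad_mask <- function(x, mask, tape) {
  ad_node(tape, x$value * mask, parents = list(x),
          backward = function(nd) ad_accum(nd$parents[[1]], nd$grad * mask))
}

#' Outer sum of two N x 1 nodes: s 1' + 1 d' (N x N). Used by the dense
#' masked-attention (GAT) ablation encoder.
#' @keywords internal
ad_outer_sum <- function(s, d, tape) {
  sv <- as.numeric(s$value); dv <- as.numeric(d$value)
  ad_node(tape, outer(sv, rep(1, length(dv))) + outer(rep(1, length(sv)), dv),
          parents = list(s, d),
          backward = function(nd) {
            gs <- rowSums(nd$grad); dim(gs) <- c(length(gs), 1L)
            gd <- colSums(nd$grad); dim(gd) <- c(length(gd), 1L)
            ad_accum(nd$parents[[1]], gs)
            ad_accum(nd$parents[[2]], gd)
          })
}

#' @keywords internal
ad_leakyrelu <- function(x, tape, slope = 0.2) {
  fac <- ifelse(x$value > 0, 1, slope)
  ad_node(tape, x$value * fac, parents = list(x),
          backward = function(nd) ad_accum(nd$parents[[1]], nd$grad * fac))
}

#' Row softmax restricted to a 0/1 mask; masked-out entries get weight 0.
#' Rows whose mask is all-zero yield all-zero weights.
#' @keywords internal
ad_masked_softmax_rows <- function(x, mask, tape) {
  X <- ifelse(mask > 0, x$value, -Inf)
  m <- apply(X, 1L, max)
  m[!is.finite(m)] <- 0
  e <- exp(X - m) * (mask > 0)
  rs <- rowSums(e)
  rs[rs == 0] <- 1
  p <- e / rs
  ad_node(tape, p, parents = list(x),
          backward = function(nd) {
            G <- nd$grad
            ad_accum(nd$parents[[1]], p * (G - rowSums(G * p)))
          })
}

#' Backpropagate from `node`, seeding with `seed_grad`.
#'
#' Returns a named list of gradients for every parameter leaf reached,
#' keyed by the leaf's `param_name`.
#' @keywords internal
ad_backward <- function(tape, node, seed_grad) {
  node$grad <- seed_grad
  grads <- list()
  for (i in seq(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad)) next
    if (!is.null(nd$backward)) nd$backward(nd)
    if (!is.null(nd$param_name)) {
      if (is.null(grads[[nd$param_name]])) {
        grads[[nd$param_name]] <- nd$grad
      } else {
        grads[[nd$param_name]] <- grads[[nd$param_name]] + nd$grad
      }
    }
  }
  grads
}
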