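#' Model and training configuration
#'
#' Collects every architectural and training hyperparameter, with defaults
#' matching the reference setting: omics encoders 16 -> 96 -> 256,
#' attention width 64, projection 128, a 6-layer width-200 GCN classifier
#' head, dropout 0.2, AdamW at learning rate 0.00055 with weight decay
#' 8e-5, 900 epochs, distillation weight 0.5, a 6-member student ensemble
#' with integration temperature 0.08, and a 10-teacher distillation
#' ensemble (encoders 128 -> 512, 1200 epochs, lr 3e-4, weight decay 5e-5,
#' dropout 0.15, early-stopping patience 200, parameter EMA decay 0.995).
#'
#' @param ... overrides of any default field (unknown names are an error).
#' @return A `model_config` list.
#' @export
model_config <- function(...) {
  cfg <- list(
    # encoders
    hidden1 = 96L, hidden2 = 256L,
    encoder_type = "residual_gcn",   # residual_gcn | sage_shared | gat
    expression_pair_input = FALSE,
    active_blocks = c("mutation", "expression", "methylation", "cnv"),
    # attention fusion
    fusion = "attention",            # attention | sum
    d_a = 64L, attention_sigma = "tanh",
    # enhancement
    use_structural = TRUE, use_walks = TRUE, use_teacher = TRUE,
    walk_p = 1, walk_q = 1, walk_length = 80L, walks_per_node = 10L,
    walk_window = 10L, walk_dim = 32L,
    # heads
    head = "dual",                   # dual | gcn_only
    proj_dim = 128L, gcn_head_width = 200L, gcn_head_depth = 6L,
    mlp_head_widths = c(256L, 128L, 64L),
    dropout = 0.2,
    # objective
    lambda_kd = 0.5, class_weights = "auto",
    use_focal = FALSE, focal_gamma = 2,
    distill_include_unlabeled = TRUE,
    # augmentation
    augment_enabled = TRUE, feature_mask_rate = 0.1, edge_drop_rate = 0.1,
    # optimization
    lr = 0.00055, weight_decay = 8e-5, epochs = 900L,
    # student ensembling
    n_student_ensemble = 6L, ensemble_temperature = 0.08,
    ensemble_mode = "softmax",       # softmax | mean
    val_fraction = 0.1, eval_every = 10L, patience = Inf,
    # teacher ensemble
    teacher = list(hidden1 = 128L, hidden2 = 512L, epochs = 1200L,
                   lr = 3e-4, weight_decay = 5e-5, dropout = 0.15,
                   patience = 200L, ema_decay = 0.995, n_teachers = 10L)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(cfg), "teacher"))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  tidx <- which(names(dots) == "teacher")
  for (i in tidx) cfg$teacher <- utils::modifyList(cfg$teacher, dots[[i]])
  if (length(tidx)) dots <- dots[-tidx]
  cfg[names(dots)] <- dots
  structure(cfg, class = "model_config")
}

block_index <- c(mutation = 1L, expression = 2L, methylation = 3L, cnv = 4L)
paired_block <- c(mutation = "mutation", methylation = "methylation",
                  cnv = "cnv")

#' Initialize all model parameters
#'
#' @param config a [model_config()].
#' @param d_extra width of the enhancement block `X_extra` (0 disables the
#'   enhancement MLP).
#' @return flat named list of parameter matrices.
#' @export
init_model_params <- function(config, d_extra = 0L) {
  h1 <- config$hidden1; h2 <- config$hidden2
  p <- list()
  if (config$encoder_type == "sage_shared") {
    p$shared <- init_sage_encoder(16L * length(config$active_blocks), h1, h2)
  } else {
    init_enc <- if (config$encoder_type == "gat") init_gat_encoder
                else init_encoder
    for (b in config$active_blocks) {
      if (b == "expression") {
        d_in <- if (isTRUE(config$expression_pair_input)) 32L else 16L
        for (v in c("e21", "e23", "e24")) {
          p[[paste0("enc_", v)]] <- init_enc(d_in, h1, h2)
          p[[paste0("mlp_", v)]] <- init_mlp(c(h2, 256L, h2))
        }
        p$expr_fuse <- list(W = glorot(3L * h2, h2), b = zeros_row(h2))
      } else {
        p[[paste0("enc_", b)]] <- init_enc(16L, h1, h2)
      }
    }
    if (config$fusion == "attention" && length(config$active_blocks) > 1L) {
      p$att <- init_attention(h2, config$d_a)
    }
  }
  if (d_extra > 0L) p$mx <- init_enhance_mlp(as.integer(d_extra), h2)
  p$heads <- init_heads(h2, config$proj_dim, config$gcn_head_width,
                        config$gcn_head_depth, config$mlp_head_widths)
  flatten_params(p)
}

# operators the encoders need, derived from a raw 0/1 sparse adjacency
graph_operators <- function(A, config) {
  ops <- list(adnorm = normalize_operator(A))
  if (config$encoder_type == "sage_shared") {
    ops$mean_adj <- mean_adjacency(A)
  }
  if (config$encoder_type == "gat") {
    ops$gat_mask <- as.matrix(A) + diag(nrow(A))
  }
  ops
}

#' Full forward pass of the model
#'
#' Encoders -> fusion -> enhancement -> dual heads, on the tape. Internal
#' workhorse; [predict_model()] is the user-facing entry point.
#'
#' @param params flat parameter list.
#' @param config a [model_config()].
#' @param X N x 64 standardized feature matrix.
#' @param ops operator list from `graph_operators`.
#' @param X_extra standardized enhancement block or NULL.
#' @param training enables dropout (and expects augmented `ops`).
#' @return list with tape nodes (`logits`, `yG`, `ym`) plus
#'   `attention_weights` and the `tape`/`ctx` for backward.
#' @keywords internal
model_forward <- function(params, config, X, ops, X_extra = NULL,
                          training = FALSE) {
  tape <- ad_tape()
  ctx <- fwd_ctx(params, tape)
  slices <- omics_block_slices()
  att_w <- NULL

  if (config$encoder_type == "sage_shared") {
    cols <- unlist(slices[config$active_blocks], use.names = FALSE)
    fused <- sage_forward(ctx, "shared", X[, cols, drop = FALSE],
                          ops$mean_adj)
  } else {
    enc_fun <- switch(config$encoder_type,
                      residual_gcn = function(pre, Xb)
                        encoder_forward(ctx, pre, Xb, ops$adnorm),
                      gat = function(pre, Xb)
                        gat_forward(ctx, pre, Xb, ops$gat_mask),
                      stop("unknown encoder_type: ", config$encoder_type))
    Hs <- list()
    for (b in config$active_blocks) {
      if (b == "expression") {
        Xe <- X[, slices$expression, drop = FALSE]
        views <- list(e21 = "mutation", e23 = "methylation", e24 = "cnv")
        outs <- lapply(names(views), function(v) {
          Xin <- if (isTRUE(config$expression_pair_input)) {
            cbind(Xe, X[, slices[[views[[v]]]], drop = FALSE])
          } else Xe
          hv <- enc_fun(paste0("enc_", v), Xin)
          mlp_forward(ctx, paste0("mlp_", v), hv, 2L)
        })
        cc <- ad_concat_cols(outs, tape)
        Hs$expression <- ad_add_bias(
          ad_matmul(cc, pget(ctx, "expr_fuse.W"), tape),
          pget(ctx, "expr_fuse.b"), tape)
      } else {
        Hs[[b]] <- enc_fun(paste0("enc_", b), X[, slices[[b]], drop = FALSE])
      }
    }
    Hs <- Hs[config$active_blocks]
    if (length(Hs) == 1L) {
      fused <- Hs[[1L]]
    } else if (config$fusion == "attention") {
      af <- attention_forward(ctx, "att", Hs, config$attention_sigma)
      fused <- af$fused
      att_w <- af$weights
      colnames(att_w) <- names(Hs)
    } else {
      fused <- Reduce(function(a, b) ad_add(a, b, tape), Hs)
    }
  }

  if (!is.null(X_extra)) {
    extra <- mlp_forward(ctx, "mx", X_extra, 2L)
    fused <- ad_add(fused, extra, tape)
  }

  out <- heads_forward(ctx, fused, ops$adnorm, config, training)
  list(tape = tape, ctx = ctx, logits = out$logits, yG = out$yG,
       ym = out$ym, attention_weights = att_w)
}

# -- AdamW --------------------------------------------------------------------

adamw_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

# -- training -----------------------------------------------------------------

#' Train a model transductively
#'
#' Full-batch training of the complete forward path with the combined
#' class-balanced BCE (or focal) + distillation objective, AdamW updates,
#' optional feature-mask/edge-drop augmentation, optional parameter EMA,
#' and optional early stopping on validation average precision.
#'
#' @param graph a normalized [gene_graph()].
#' @param X N x 64 standardized feature matrix (train-fold statistics).
#' @param y full-length label vector (1/0/NA from [label_vector()]).
#' @param train_idx labeled node indices the task loss is computed on.
#' @param config a [model_config()].
#' @param X_extra standardized enhancement block or NULL.
#' @param teacher_logits teacher soft labels (length N) or NULL; enables
#'   the distillation loss when `config$lambda_kd > 0`.
#' @param val_idx labeled indices for early stopping / ensemble weighting
#'   (never part of `train_idx`).
#' @param epochs overrides `config$epochs`.
#' @param ema_decay parameter EMA decay (0 disables; final parameters are
#'   the EMA when enabled).
#' @param patience early-stopping patience in epochs (Inf disables);
#'   requires `val_idx`.
#' @param lr,weight_decay,dropout optional overrides.
#' @param verbose print a line every 50 epochs.
#' @return list of class `gnn_model`: `params`, `config`, `history`,
#'   `val_auprc`, `ops` (clean operators), `d_extra`.
#' @export
train_model <- function(graph, X, y, train_idx, config = model_config(),
                        X_extra = NULL, teacher_logits = NULL,
                        val_idx = NULL, epochs = NULL, ema_decay = 0,
                        patience = NULL, lr = NULL, weight_decay = NULL,
                        dropout = NULL, verbose = FALSE) {
  epochs <- if (is.null(epochs)) config$epochs else as.integer(epochs)
  lr <- if (is.null(lr)) config$lr else lr
  weight_decay <- if (is.null(weight_decay)) config$weight_decay
                  else weight_decay
  if (!is.null(dropout)) config$dropout <- dropout
  patience <- if (is.null(patience)) config$patience else patience
  if (is.finite(patience) && is.null(val_idx)) {
    stop("early stopping requires val_idx")
  }
  if (length(intersect(train_idx, val_idx))) {
    stop("train and validation indices overlap")
  }
  y_tr <- y[train_idx]
  if (anyNA(y_tr)) stop("train_idx contains unlabeled nodes")
  weights <- if (identical(config$class_weights, "auto")) {
    auto_class_weights(y_tr)
  } else config$class_weights
  use_kd <- !is.null(teacher_logits) && config$lambda_kd > 0
  if (use_kd) {
    M <- if (isTRUE(config$distill_include_unlabeled)) {
      sort(union(train_idx, which(is.na(y))))
    } else train_idx
  }
  d_extra <- if (is.null(X_extra)) 0L else ncol(X_extra)
  params <- init_model_params(config, d_extra)
  state <- adamw_state(params)
  ema <- if (ema_decay > 0) params else NULL
  ops_clean <- graph_operators(graph$adjacency, config)
  history <- numeric(epochs)
  best <- list(score = -Inf, params = NULL, epoch = 0L)
  n_eval_since <- 0L

  for (ep in seq_len(epochs)) {
    if (isTRUE(config$augment_enabled) &&
        (config$feature_mask_rate > 0 || config$edge_drop_rate > 0)) {
      aug <- augment_full(X, graph, config)
      Xe <- aug$X; ops <- aug$ops
    } else {
      Xe <- X; ops <- ops_clean
    }
    fw <- model_forward(params, config, Xe, ops, X_extra, training = TRUE)
    logits <- as.numeric(fw$logits$value)
    lt <- logits[train_idx]
    task <- if (isTRUE(config$use_focal)) {
      focal_loss(lt, y_tr, config$focal_gamma, weights)
    } else {
      balanced_bce(lt, y_tr, weights)
    }
    kd <- if (use_kd) kd_loss(logits, teacher_logits, M) else 0
    rep_loss <- total_loss(task, kd, config$lambda_kd)
    if (!is.finite(rep_loss$total)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
    }
    history[ep] <- rep_loss$total
    g <- numeric(length(y))
    g[train_idx] <- if (isTRUE(config$use_focal)) {
      focal_loss_grad(lt, y_tr, config$focal_gamma, weights)
    } else {
      balanced_bce_grad(lt, y_tr, weights)
    }
    if (use_kd) {
      g <- g + config$lambda_kd * kd_loss_grad(logits, teacher_logits, M)
    }
    grads <- ad_backward(fw$tape, fw$logits, matrix(g, ncol = 1L))
    upd <- adamw_step(params, grads, state, lr, weight_decay)
    params <- upd$params; state <- upd$state
    if (!is.null(ema)) {
      for (nm in names(params)) {
        ema[[nm]] <- ema_decay * ema[[nm]] + (1 - ema_decay) * params[[nm]]
      }
    }
    if (!is.null(val_idx) && length(val_idx) &&
        (ep %% config$eval_every == 0L || ep == epochs)) {
      pe <- if (is.null(ema)) params else ema
      fv <- model_forward(pe, config, X, ops_clean, X_extra,
                          training = FALSE)
      sc <- compute_metrics(as.numeric(fv$logits$value)[val_idx],
                            y[val_idx])
      if (sc[["auprc"]] > best$score) {
        best <- list(score = sc[["auprc"]], params = pe, epoch = ep)
        n_eval_since <- 0L
      } else {
        n_eval_since <- n_eval_since + config$eval_every
        if (n_eval_since >= patience) break
      }
    }
    if (verbose && ep %% 50L == 0L) {
      message(sprintf("epoch %d: loss %.4f (task %.4f, kd %.4f)",
                      ep, rep_loss$total, task, kd))
    }
  }

  final <- if (is.finite(patience) && !is.null(best$params)) {
    best$params
  } else if (!is.null(ema)) ema else params
  val_auprc <- if (!is.null(val_idx) && length(val_idx)) {
    fv <- model_forward(final, config, X, ops_clean, X_extra,
                        training = FALSE)
    compute_metrics(as.numeric(fv$logits$value)[val_idx],
                    y[val_idx])[["auprc"]]
  } else NA_real_
  structure(list(params = final, config = config, history = history,
                 val_auprc = val_auprc, d_extra = d_extra),
            class = "gnn_model")
}

augment_full <- function(X, graph, config) {
  Xp <- X
  if (config$feature_mask_rate > 0) {
    Xp <- Xp * (matrix(stats::runif(length(X)), nrow(X)) >=
                  config$feature_mask_rate)
  }
  e <- graph$edges
  if (config$edge_drop_rate > 0 && nrow(e) > 0) {
    e <- e[stats::runif(nrow(e)) >= config$edge_drop_rate, , drop = FALSE]
  }
  A <- edges_to_adjacency(e, length(graph$symbols))
  list(X = Xp, ops = graph_operators(A, config))
}

edges_to_adjacency <- function(e, n) {
  if (nrow(e) > 0) {
    Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                         x = 1, dims = c(n, n))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  }
}

#' Predict with a trained model
#'
#' Evaluation-mode forward pass on the clean (non-augmented) graph.
#'
#' @param model a [train_model()] result.
#' @param graph the [gene_graph()] used for training.
#' @param X standardized N x 64 feature matrix.
#' @param X_extra standardized enhancement block or NULL.
#' @return list with `logits`, `probabilities`, `head_logits`,
#'   `attention_weights`.
#' @export
predict_model <- function(model, graph, X, X_extra = NULL) {
  ops <- graph_operators(graph$adjacency, model$config)
  fw <- model_forward(model$params, model$config, X, ops, X_extra,
                      training = FALSE)
  logits <- as.numeric(fw$logits$value)
  list(logits = logits,
       probabilities = sigmoid_probability(logits),
       head_logits = list(
         yG = as.numeric(fw$yG$value),
         ym = if (is.null(fw$ym)) NULL else as.numeric(fw$ym$value)),
       attention_weights = fw$attention_weights)
}
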