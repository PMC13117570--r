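# Evaluation protocol: ranking metrics, repeated stratified k-fold
# cross-validation with fold-aware standardization and per-fold teachers,
# student ensembling, negative-sampling-ratio experiments, and the
# ablation registry.

#' Ranking metrics for imbalanced binary labels
#'
#' AUROC via the rank statistic with tie midranks; AUPRC as the step-wise
#' precision-recall integral (average precision, no trapezoid), with tied
#' scores grouped into one threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector.
#' @return named numeric vector `c(auroc, auprc)`.
#' @export
compute_metrics <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  # group tied scores into single thresholds, descending
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tp_g)
  npred <- cumsum(n_g)
  prec <- tp / npred
  rec <- tp / np
  drec <- diff(c(0, rec))
  auprc <- sum(prec * drec)
  c(auroc = auroc, auprc = unname(auprc))
}

#' Repeated stratified k-fold plan over labeled nodes
#'
#' Within each repeat the test folds partition the labeled nodes and each
#' fold preserves the positive fraction to within one node.
#'
#' @param labels a [label_set()].
#' @param n_repeats,n_folds protocol shape (default 10 x 5).
#' @param seed master seed; each repeat derives its own shuffle seed.
#' @return list of folds, each with `train_idx`, `test_idx`, `repeat_id`,
#'   `fold_id`; class `fold_plan`.
#' @export
fold_plan <- function(labels, n_repeats = 10L, n_folds = 5L, seed = 1L) {
  pos <- labels$positives
  neg <- labels$negatives
  if (length(pos) < n_folds || length(neg) < n_folds) {
    stop("too few labeled nodes per class for ", n_folds, " folds")
  }
  plan <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, 11L, r))
    fp <- sample(rep_len(seq_len(n_folds), length(pos)))
    fn <- sample(rep_len(seq_len(n_folds), length(neg)))
    for (f in seq_len(n_folds)) {
      test <- sort(c(pos[fp == f], neg[fn == f]))
      train <- sort(c(pos[fp != f], neg[fn != f]))
      plan[[length(plan) + 1L]] <- list(train_idx = train, test_idx = test,
                                        repeat_id = r, fold_id = f)
    }
  }
  structure(plan, class = "fold_plan",
            n_repeats = n_repeats, n_folds = n_folds, seed = seed)
}

#' Temperature-weighted student ensembling
#'
#' Combines member logits as `sum_k softmax(val_auprc / T)_k * logit_k`;
#' `mode = "mean"` (the T -> Inf limit) is the plain average.
#'
#' @param logits_list list of length-N member logit vectors.
#' @param val_scores validation average precision per member.
#' @param temperature integration temperature (default 0.08).
#' @param mode `"softmax"` or `"mean"`.
#' @return list with `logits` (combined) and `weights`.
#' @export
ensemble_students <- function(logits_list, val_scores = NULL,
                              temperature = 0.08,
                              mode = c("softmax", "mean")) {
  mode <- match.arg(mode)
  k <- length(logits_list)
  if (k == 0L) stop("empty ensemble")
  w <- if (mode == "mean" || k == 1L || is.null(val_scores)) {
    rep(1 / k, k)
  } else {
    z <- val_scores / temperature
    e <- exp(z - max(z))
    e / sum(e)
  }
  m <- do.call(cbind, logits_list)
  list(logits = as.numeric(m %*% w), weights = w)
}

# fit-and-apply fold standardization for the omics and enhancement blocks
standardize_fold <- function(X, extra_raw, train_rows) {
  st <- fit_standardizer(X, train_rows)
  out <- list(X = apply_standardizer(X, st), stats = st)
  if (!is.null(extra_raw)) {
    st2 <- fit_standardizer(extra_raw, train_rows)
    out$extra <- apply_standardizer(extra_raw, st2)
    out$extra_stats <- st2
  }
  out
}

# unsupervised full-graph features shared across folds (label-free)
compute_graph_features <- function(graph, config, seed) {
  list(
    structural = if (config$use_structural) {
      structural_features(graph)$values
    } else NULL,
    walks = if (config$use_walks) {
      node2vec_embed(graph, p = config$walk_p, q = config$walk_q,
                     walk_length = config$walk_length,
                     walks_per_node = config$walks_per_node,
                     window = config$walk_window, dim = config$walk_dim,
                     seed = derive_seed(seed, 29L))$values
    } else NULL)
}

# train teachers + student ensemble on one fold; returns test predictions
run_fold <- function(graph, X_raw, y, fold, config, feats, seed,
                     epochs = NULL, teacher_epochs = NULL,
                     n_teachers = NULL, n_students = NULL,
                     neg_ratio = NULL) {
  train_idx <- fold$train_idx
  test_idx <- fold$test_idx
  if (!is.null(neg_ratio) && !identical(neg_ratio, "all")) {
    pos <- train_idx[y[train_idx] == 1]
    neg <- train_idx[y[train_idx] == 0]
    n_keep <- min(length(neg), ceiling(neg_ratio * length(pos)))
    if (n_keep < length(neg)) {
      set.seed(derive_seed(seed, 37L, fold$repeat_id * 100L + fold$fold_id))
      neg <- sort(sample(neg, n_keep))
    }
    train_idx <- sort(c(pos, neg))
  }
  needs_teacher <- config$use_teacher || config$lambda_kd > 0
  extra_unsup <- enhancement_bundle(
    structural = feats$structural, walks = feats$walks,
    use_structural = config$use_structural, use_walks = config$use_walks,
    use_teacher = FALSE)
  sf <- standardize_fold(X_raw, extra_unsup, train_idx)
  X <- sf$X
  soft <- NULL
  if (needs_teacher) {
    soft <- distill_soft_labels(
      graph, X, y, train_idx, config,
      seed = derive_seed(seed, 53L, fold$repeat_id * 100L + fold$fold_id),
      X_extra = sf$extra, epochs = teacher_epochs,
      n_teachers = n_teachers)$logits
  }
  extra_full <- enhancement_bundle(
    structural = feats$structural, walks = feats$walks,
    teacher_logits = soft,
    use_structural = config$use_structural, use_walks = config$use_walks,
    use_teacher = config$use_teacher && !is.null(soft))
  X_extra <- if (is.null(extra_full)) NULL else {
    apply_standardizer(extra_full, fit_standardizer(extra_full, train_idx))
  }
  teacher_for_kd <- if (config$lambda_kd > 0) soft else NULL
  n_students <- if (is.null(n_students)) config$n_student_ensemble
                else as.integer(n_students)
  members <- vector("list", n_students)
  val_scores <- numeric(n_students)
  for (k in seq_len(n_students)) {
    sk <- derive_seed(seed, 91L,
                      fold$repeat_id * 10000L + fold$fold_id * 100L + k)
    set.seed(sk)
    sp <- carve_validation(y, train_idx, config$val_fraction)
    model <- train_model(graph, X, y, sp$train, config, X_extra = X_extra,
                         teacher_logits = teacher_for_kd, val_idx = sp$val,
                         epochs = epochs)
    pred <- predict_model(model, graph, X, X_extra)
    members[[k]] <- pred$logits
    val_scores[k] <- model$val_auprc
  }
  ens <- ensemble_students(members, val_scores,
                           temperature = config$ensemble_temperature,
                           mode = config$ensemble_mode)
  list(logits = ens$logits,
       metrics = compute_metrics(ens$logits[test_idx], y[test_idx]),
       test_idx = test_idx,
       std_source_rows = sf$stats$source_rows,
       train_idx = train_idx)
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' Per fold: standardization statistics are fitted on the training fold
#' only; teachers are (re)trained on the training fold (leak-free default);
#' the student ensemble is trained with the combined objective and
#' evaluated on the untouched test fold by AUROC/AUPRC.
#'
#' @param graph normalized [gene_graph()].
#' @param omics an [omics_matrix()] (raw, unstandardized).
#' @param labels a [label_set()].
#' @param config a [model_config()].
#' @param n_repeats,n_folds protocol shape.
#' @param seed master seed; folds, teachers, students, augmentation and
#'   walks all derive from it.
#' @param epochs,teacher_epochs,n_teachers,n_students optional reduced
#'   budgets for desk-scale runs (defaults come from `config`).
#' @param neg_ratio training-fold negative:positive subsampling ratio
#'   (numeric) or `"all"` (default; no subsampling).
#' @return list of class `cv_report`: `per_fold` (data.frame with
#'   repeat/fold/auroc/auprc), `mean`, `sd`, `fold_details`.
#' @export
cross_validate <- function(graph, omics, labels, config = model_config(),
                           n_repeats = 10L, n_folds = 5L, seed = 1L,
                           epochs = NULL, teacher_epochs = NULL,
                           n_teachers = NULL, n_students = NULL,
                           neg_ratio = "all") {
  stopifnot(inherits(omics, "omics_matrix"))
  if (isTRUE(omics$standardized)) {
    stop("pass raw features; standardization is fold-aware")
  }
  y <- label_vector(labels)
  plan <- fold_plan(labels, n_repeats, n_folds, seed)
  feats <- compute_graph_features(graph, config, seed)
  res <- lapply(plan, function(fold) {
    run_fold(graph, omics$values, y, fold, config, feats, seed,
             epochs = epochs, teacher_epochs = teacher_epochs,
             n_teachers = n_teachers, n_students = n_students,
             neg_ratio = neg_ratio)
  })
  per_fold <- data.frame(
    repeat_id = vapply(plan, `[[`, integer(1), "repeat_id"),
    fold_id = vapply(plan, `[[`, integer(1), "fold_id"),
    auroc = vapply(res, function(r) r$metrics[["auroc"]], numeric(1)),
    auprc = vapply(res, function(r) r$metrics[["auprc"]], numeric(1)))
  structure(list(per_fold = per_fold,
                 mean = c(auroc = mean(per_fold$auroc),
                          auprc = mean(per_fold$auprc)),
                 sd = c(auroc = stats::sd(per_fold$auroc),
                        auprc = stats::sd(per_fold$auprc)),
                 fold_details = res),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds\n", nrow(x$per_fold)))
  cat(sprintf("  AUROC %.4f +/- %.4f\n", x$mean[["auroc"]],
              ifelse(is.na(x$sd[["auroc"]]), 0, x$sd[["auroc"]])))
  cat(sprintf("  AUPRC %.4f +/- %.4f\n", x$mean[["auprc"]],
              ifelse(is.na(x$sd[["auprc"]]), 0, x$sd[["auprc"]])))
  invisible(x)
}

#' Negative-sampling-ratio sensitivity experiment
#'
#' Re-runs [cross_validate()] with the training-fold negatives subsampled
#' to each requested negative:positive ratio (test folds untouched).
#'
#' @inheritParams cross_validate
#' @param ratios list/vector of numeric ratios and/or `"all"`.
#' @return named list of `cv_report`s, one per ratio.
#' @export
negative_sampling_experiment <- function(graph, omics, labels,
                                         config = model_config(),
                                         ratios = list(1, 2, 5, "all"),
                                         ...) {
  out <- lapply(ratios, function(r) {
    cross_validate(graph, omics, labels, config, neg_ratio = r, ...)
  })
  names(out) <- vapply(ratios, function(r) {
    if (identical(r, "all")) "all" else paste0("ratio_", r)
  }, character(1))
  out
}

#' Ablation variant registry
#'
#' Named configuration mutations matching the ablation table: omics-block
#' subsets, shared-SAGE / GAT encoders, sum fusion, GCN-only head,
#' enhancement-source toggles, and the teacher/distillation decomposition.
#'
#' @return named list of functions `config -> config`.
#' @export
ablation_registry <- function() {
  blocks <- function(...) {
    keep <- c(...)
    function(cfg) { cfg$active_blocks <- keep; cfg }
  }
  list(
    "XM+XT" = blocks("mutation", "methylation"),
    "XM+XE+XT" = blocks("mutation", "expression", "methylation"),
    "XM+XE+XC" = blocks("mutation", "expression", "cnv"),
    "XE+XT+XC" = blocks("expression", "methylation", "cnv"),
    "XM+XE+XT+XC" = function(cfg) cfg,
    "without_independent_encoding" = function(cfg) {
      cfg$encoder_type <- "sage_shared"; cfg
    },
    "independent_encoding_by_gat" = function(cfg) {
      cfg$encoder_type <- "gat"; cfg
    },
    "without_attention_layer" = function(cfg) { cfg$fusion <- "sum"; cfg },
    "predict_by_gcn" = function(cfg) { cfg$head <- "gcn_only"; cfg },
    "without_structural_features" = function(cfg) {
      cfg$use_structural <- FALSE; cfg
    },
    "without_node2vec_embedding" = function(cfg) {
      cfg$use_walks <- FALSE; cfg
    },
    "without_teacher_model" = function(cfg) {
      cfg$use_teacher <- FALSE; cfg$lambda_kd <- 0; cfg
    },
    "teacher_logits_only" = function(cfg) {
      cfg$use_teacher <- TRUE; cfg$lambda_kd <- 0; cfg
    },
    "distillation_loss_only" = function(cfg) {
      cfg$use_teacher <- FALSE; cfg$lambda_kd <- 0.5; cfg
    },
    "without_feature_enhancement" = function(cfg) {
      cfg$use_structural <- FALSE; cfg$use_walks <- FALSE
      cfg$use_teacher <- FALSE; cfg$lambda_kd <- 0; cfg
    })
}

#' Run one ablation variant through cross-validation
#'
#' @inheritParams cross_validate
#' @param variant a name from [ablation_registry()].
#' @return a `cv_report`.
#' @export
run_ablation <- function(variant, graph, omics, labels,
                         config = model_config(), ...) {
  reg <- ablation_registry()
  if (!variant %in% names(reg)) {
    stop("unknown ablation variant '", variant, "'; registry: ",
         paste(names(reg), collapse = ", "))
  }
  cross_validate(graph, omics, labels, reg[[variant]](config), ...)
}

#' Write a ranked prediction table
#'
#' TSV with gene, per-head logits, combined logit and probability, sorted
#' by probability descending; optionally truncated to the top k candidates.
#'
#' @param pred a [predict_model()] result.
#' @param graph the matching [gene_graph()].
#' @param path output TSV path.
#' @param top_k optional truncation.
#' @param dump_attention optional path for the per-gene attention weights.
#' @return the path, invisibly.
#' @export
write_predictions <- function(pred, graph, path, top_k = NULL,
                              dump_attention = NULL) {
  tb <- data.frame(gene = graph$symbols,
                   logit_gcn = pred$head_logits$yG,
                   logit_mlp = if (is.null(pred$head_logits$ym)) NA_real_
                               else pred$head_logits$ym,
                   logit = pred$logits,
                   probability = pred$probabilities)
  tb <- tb[order(-tb$probability), ]
  if (!is.null(top_k)) tb <- utils::head(tb, top_k)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dump_attention) && !is.null(pred$attention_weights)) {
    aw <- data.frame(gene = graph$symbols, pred$attention_weights)
    utils::write.table(aw, dump_attention, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
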