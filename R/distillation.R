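# Teacher ensemble and knowledge distillation: high-capacity teachers are
# trained with the class-balanced BCE only (no distillation), their
# parameter EMA is used for the final logits, and the ensemble mean of the
# per-teacher logits becomes the soft labels the student consumes.

teacher_config <- function(config) {
  tc <- config$teacher
  model_config(hidden1 = tc$hidden1, hidden2 = tc$hidden2,
               encoder_type = config$encoder_type,
               active_blocks = config$active_blocks,
               fusion = config$fusion, head = config$head,
               dropout = tc$dropout,
               use_structural = config$use_structural,
               use_walks = config$use_walks,
               use_teacher = FALSE, lambda_kd = 0,
               lr = tc$lr, weight_decay = tc$weight_decay,
               epochs = tc$epochs,
               augment_enabled = config$augment_enabled,
               feature_mask_rate = config$feature_mask_rate,
               edge_drop_rate = config$edge_drop_rate,
               eval_every = config$eval_every,
               teacher = config$teacher)
}

#' Train one teacher model and emit its logits for all nodes
#'
#' The teacher shares the student's multi-encoder architecture at higher
#' capacity (encoder widths from `config$teacher`), trains with the
#' class-balanced BCE only, keeps an exponential moving average of its
#' parameters, stops early on validation average precision, and returns
#' EMA-parameter logits for every node. A 10% validation subset is carved
#' from the training labels for the stopping criterion; the loss sees only
#' the remaining 90%.
#'
#' @param graph normalized [gene_graph()].
#' @param X standardized N x 64 feature matrix (train-fold statistics).
#' @param y full-length 1/0/NA label vector.
#' @param train_idx labeled node indices of the training fold.
#' @param config a [model_config()]; teacher hyperparameters are read from
#'   its `teacher` field.
#' @param seed RNG seed for this teacher.
#' @param X_extra standardized unsupervised enhancement block (structural
#'   metrics + walk embeddings; never teacher logits) or NULL.
#' @param epochs optional override of the teacher epoch budget.
#' @return list with `logits` (length N) and the fitted `model`.
#' @export
train_teacher <- function(graph, X, y, train_idx, config = model_config(),
                          seed = 1L, X_extra = NULL, epochs = NULL) {
  tc <- config$teacher
  tcfg <- teacher_config(config)
  set.seed(seed)
  sp <- carve_validation(y, train_idx, config$val_fraction)
  model <- train_model(graph, X, y, sp$train, tcfg, X_extra = X_extra,
                       teacher_logits = NULL, val_idx = sp$val,
                       epochs = if (is.null(epochs)) tc$epochs else epochs,
                       ema_decay = tc$ema_decay, patience = tc$patience)
  pred <- predict_model(model, graph, X, X_extra)
  list(logits = pred$logits, model = model)
}

# stratified carve of a validation subset from the training labels
carve_validation <- function(y, train_idx, fraction) {
  pos <- train_idx[y[train_idx] == 1]
  neg <- train_idx[y[train_idx] == 0]
  nvp <- max(1L, round(fraction * length(pos)))
  nvn <- max(1L, round(fraction * length(neg)))
  val <- c(sample(pos, nvp), sample(neg, nvn))
  list(train = sort(setdiff(train_idx, val)), val = sort(val))
}

#' Average per-teacher logits into soft labels
#'
#' @param per_teacher list of length-N numeric logit vectors (>= 1).
#' @return list with `logits` (ensemble mean, length N) and
#'   `per_teacher_logits` (N x n_teachers matrix).
#' @export
ensemble_soft_labels <- function(per_teacher) {
  if (length(per_teacher) == 0L) stop("need at least one teacher")
  lens <- unique(lengths(per_teacher))
  if (length(lens) != 1L) stop("teacher logit vectors disagree in length")
  m <- do.call(cbind, per_teacher)
  list(logits = rowMeans(m), per_teacher_logits = m)
}

#' Train the full teacher ensemble and distill soft labels
#'
#' Trains `n_teachers` teachers (differing only by seed) on the training
#' fold and averages their all-node logits.
#'
#' @inheritParams train_teacher
#' @param seeds integer vector of per-teacher seeds (length = n_teachers);
#'   defaults are derived deterministically from `seed`.
#' @param n_teachers overrides `config$teacher$n_teachers`.
#' @return list with `logits`, `per_teacher_logits`, `seeds`.
#' @export
distill_soft_labels <- function(graph, X, y, train_idx,
                                config = model_config(), seed = 1L,
                                X_extra = NULL, epochs = NULL,
                                n_teachers = NULL, seeds = NULL) {
  n_teachers <- if (is.null(n_teachers)) config$teacher$n_teachers
                else as.integer(n_teachers)
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_teachers), function(k) derive_seed(seed, 71L, k),
                    integer(1))
  }
  per <- lapply(seeds, function(s) {
    train_teacher(graph, X, y, train_idx, config, seed = s,
                  X_extra = X_extra, epochs = epochs)$logits
  })
  out <- ensemble_soft_labels(per)
  out$seeds <- seeds
  out
}

# deterministic seed fan-out; stays below 2^31
derive_seed <- function(master, stream, k = 0L) {
  as.integer((as.numeric(master) * 48271 + stream * 69621 + k * 16807) %%
               2147483647)
}
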