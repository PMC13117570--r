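# Losses: class-balanced BCE, optional focal loss, soft-label distillation,
# and the combined objective. All forms use log-sigmoid identities
# (log sigma(x) = plogis(x, log.p = TRUE)) so they stay finite for logits
# up to +/- 500.

#' Inverse-frequency class weights
#'
#' `w_p = N / (2 N_pos)`, `w_n = N / (2 N_neg)` over the labeled training
#' nodes: balanced effective mass (`w_p N_pos = w_n N_neg`), mean-preserving.
#'
#' @param y 0/1 label vector (no NAs).
#' @return named numeric vector `c(w_p, w_n)`.
#' @export
auto_class_weights <- function(y) {
  n <- length(y)
  np <- sum(y == 1)
  nn <- sum(y == 0)
  if (np == 0 || nn == 0) stop("both classes required for auto class weights")
  c(w_p = n / (2 * np), w_n = n / (2 * nn))
}

#' Class-balanced binary cross-entropy
#'
#' \eqn{-\frac{1}{N}\sum_i w_p y_i \log\sigma(\hat y_i) +
#' w_n (1-y_i)\log(1-\sigma(\hat y_i))}, computed through the numerically
#' stable log-sigmoid form.
#'
#' @param logits numeric vector of pre-sigmoid scores.
#' @param labels 0/1 vector of the same length.
#' @param weights `c(w_p, w_n)` or `"auto"` (inverse frequency).
#' @return scalar loss.
#' @export
balanced_bce <- function(logits, labels, weights = c(1, 1)) {
  n <- length(logits)
  if (n == 0L) stop("balanced_bce: empty input")
  stopifnot(length(labels) == n, all(labels %in% c(0, 1)))
  if (identical(weights, "auto")) weights <- auto_class_weights(labels)
  lp <- stats::plogis(logits, log.p = TRUE)    # log sigma(x)
  ln <- stats::plogis(-logits, log.p = TRUE)   # log (1 - sigma(x))
  -mean(weights[1L] * labels * lp + weights[2L] * (1 - labels) * ln)
}

# gradient of balanced_bce w.r.t. logits
balanced_bce_grad <- function(logits, labels, weights) {
  s <- stats::plogis(logits)
  (-(weights[1L] * labels * (1 - s)) + weights[2L] * (1 - labels) * s) /
    length(logits)
}

#' Focal loss (class-weighted)
#'
#' \eqn{-\frac{1}{N}\sum_i w_{class} (1-p_t)^\gamma \log p_t} with
#' \eqn{p_t} the predicted probability of the true class; `gamma = 0`
#' recovers [balanced_bce()] exactly.
#'
#' @inheritParams balanced_bce
#' @param gamma focusing parameter (>= 0).
#' @return scalar loss.
#' @export
focal_loss <- function(logits, labels, gamma = 2, weights = c(1, 1)) {
  stopifnot(gamma >= 0, length(labels) == length(logits))
  if (identical(weights, "auto")) weights <- auto_class_weights(labels)
  sgn <- ifelse(labels == 1, 1, -1)
  log_pt <- stats::plogis(sgn * logits, log.p = TRUE)
  pt <- exp(log_pt)
  w <- ifelse(labels == 1, weights[1L], weights[2L])
  -mean(w * (1 - pt)^gamma * log_pt)
}

focal_loss_grad <- function(logits, labels, gamma, weights) {
  sgn <- ifelse(labels == 1, 1, -1)
  log_pt <- stats::plogis(sgn * logits, log.p = TRUE)
  pt <- exp(log_pt)
  w <- ifelse(labels == 1, weights[1L], weights[2L])
  # dL/dpt, then chain through dpt/dx = sgn * pt (1 - pt)
  dldpt <- if (gamma == 0) {
    -w / pt
  } else {
    -w * (-gamma * (1 - pt)^(gamma - 1) * log_pt + (1 - pt)^gamma / pt)
  }
  dldpt * sgn * pt * (1 - pt) / length(logits)
}

#' Knowledge-distillation loss
#'
#' Mean soft-target cross-entropy over the distillation node set: the
#' teacher's sigmoid probabilities are the targets for the student's
#' sigmoid outputs. Minimized exactly when
#' \eqn{\sigma(\hat y^s) = \sigma(\hat y^t)}.
#'
#' @param student_logits,teacher_logits numeric vectors over all nodes.
#' @param node_set indices of the nodes receiving the distillation signal.
#' @param temperature optional logit scaling of the teacher (default 1:
#'   teacher probabilities used raw).
#' @return scalar loss.
#' @export
kd_loss <- function(student_logits, teacher_logits, node_set,
                    temperature = 1) {
  if (length(node_set) == 0L) stop("kd_loss: empty distillation node set")
  s <- student_logits[node_set]
  t <- stats::plogis(teacher_logits[node_set] / temperature)
  -mean(t * stats::plogis(s, log.p = TRUE) +
          (1 - t) * stats::plogis(-s, log.p = TRUE))
}

kd_loss_grad <- function(student_logits, teacher_logits, node_set,
                         temperature = 1) {
  g <- numeric(length(student_logits))
  s <- stats::plogis(student_logits[node_set])
  t <- stats::plogis(teacher_logits[node_set] / temperature)
  g[node_set] <- (s - t) / length(node_set)
  g
}

#' Combined training objective
#'
#' `L = L_task + lambda * L_KD`, reported with its decomposition.
#'
#' @param task_loss scalar task (BCE/focal) loss.
#' @param kd scalar distillation loss (0 when disabled).
#' @param lambda distillation weight (>= 0).
#' @return list with `task_loss`, `kd_loss`, `total`.
#' @export
total_loss <- function(task_loss, kd = 0, lambda = 0.5) {
  stopifnot(lambda >= 0)
  list(task_loss = task_loss, kd_loss = kd, total = task_loss + lambda * kd)
}
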