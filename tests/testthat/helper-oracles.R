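# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (dense algebra, explicit enumeration) and
# never calls the implementation paths it is used to check.

# dense reference for the self-looped symmetric normalization
dense_norm_adjacency <- function(A) {
  A <- as.matrix(A)
  Ahat <- A + diag(nrow(A))
  d <- rowSums(Ahat)
  Dinv <- diag(1 / sqrt(d), nrow(A))
  Dinv %*% Ahat %*% Dinv
}

random_gene_graph <- function(n, p_edge = 0.1) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  gene_graph(sprintf("G%03d", seq_len(n)), pairs[keep, , drop = FALSE])
}

# random graph rejected until connected (unique dominant eigenvector)
random_connected_graph <- function(n, p_edge = 0.3) {
  repeat {
    g <- random_gene_graph(n, p_edge)
    A <- as.matrix(g$adjacency)
    reach <- (diag(n) + A)
    for (i in seq_len(ceiling(log2(n)) + 1L)) reach <- reach %*% reach
    if (all(reach > 0)) return(g)
  }
}

path_graph <- function(n) {
  gene_graph(LETTERS[seq_len(n)], cbind(seq_len(n - 1L), 2:n))
}

star_graph <- function(n_leaves) {
  gene_graph(c("C", paste0("L", seq_len(n_leaves))),
             cbind(1L, 1L + seq_len(n_leaves)))
}

triangle_graph <- function() {
  gene_graph(c("A", "B", "C"), rbind(c(1, 2), c(2, 3), c(1, 3)))
}

# --- brute-force structural metrics (explicit enumeration) -------------------

bf_shortest_paths <- function(A) {
  # Floyd-Warshall distances plus shortest-path counts
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  CNT <- matrix(0, n, n)
  CNT[A > 0] <- 1
  diag(CNT) <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        alt <- D[i, k] + D[k, j]
        if (alt < D[i, j]) {
          D[i, j] <- alt
          CNT[i, j] <- CNT[i, k] * CNT[k, j]
        } else if (alt == D[i, j] && is.finite(alt) && k != i && k != j) {
          CNT[i, j] <- CNT[i, j] + CNT[i, k] * CNT[k, j]
        }
      }
    }
  }
  list(D = D, CNT = CNT)
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  sp <- bf_shortest_paths(A)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(sp$D[s, t]) || sp$CNT[s, t] == 0) next
        if (sp$D[s, v] + sp$D[v, t] == sp$D[s, t]) {
          b[v] <- b[v] + sp$CNT[s, v] * sp$CNT[v, t] / sp$CNT[s, t]
        }
      }
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

bf_closeness <- function(A) {
  # per-component convention: (reachable - 1) / sum(d to reachable)
  sp <- bf_shortest_paths(A)$D
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- sp[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
}

bf_eigenvector <- function(A, iter = 200000L) {
  n <- nrow(A)
  x <- rep(1, n)
  for (i in seq_len(iter)) {
    x2 <- as.numeric(A %*% x)
    nrm <- sqrt(sum(x2^2))
    if (nrm == 0) return(rep(0, n))
    x2 <- x2 / nrm
    if (max(abs(x2 - x)) < 1e-15) { x <- x2; break }
    x <- x2
  }
  x / max(x)
}

bf_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

bf_pagerank <- function(A, d = 0.85, iter = 20000L) {
  n <- nrow(A)
  deg <- rowSums(A)
  pr <- rep(1 / n, n)
  for (it in seq_len(iter)) {
    new <- rep((1 - d) / n, n)
    # dangling nodes distribute uniformly (igraph convention)
    dang <- sum(pr[deg == 0]) * d / n
    for (j in seq_len(n)) {
      if (deg[j] > 0) {
        tgt <- which(A[j, ] > 0)
        new[tgt] <- new[tgt] + d * pr[j] / deg[j]
      }
    }
    new <- new + dang
    if (max(abs(new - pr)) < 1e-15) { pr <- new; break }
    pr <- new
  }
  pr
}

bf_core_number <- function(A) {
  # iterative peeling
  n <- nrow(A)
  deg <- rowSums(A)
  core <- numeric(n)
  alive <- rep(TRUE, n)
  k <- 0
  while (any(alive)) {
    repeat {
      idx <- which(alive & deg <= k)
      if (length(idx) == 0) break
      core[idx] <- k
      alive[idx] <- FALSE
      for (i in idx) {
        nb <- which(A[i, ] > 0 & alive)
        deg[nb] <- deg[nb] - 1
      }
    }
    k <- k + 1
  }
  core
}

bf_structural <- function(graph) {
  A <- as.matrix(graph$adjacency)
  cbind(rowSums(A), bf_betweenness(A), bf_closeness(A), bf_eigenvector(A),
        bf_clustering(A), bf_pagerank(A), bf_core_number(A))
}

# --- brute-force ranking metrics --------------------------------------------

bf_auroc <- function(scores, labels) {
  # all-pairs concordance with 1/2 credit for ties
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

bf_auprc <- function(scores, labels) {
  # explicit precision-recall curve walk over distinct thresholds
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# --- small shared fixtures ---------------------------------------------------

std_values <- function(omics, rows) {
  apply_standardizer(omics, fit_standardizer(omics, rows))$values
}

tiny_instance <- local({
  cache <- list()
  function(n = 150L, prevalence = 0.1, signal = c(2, 2, 2, 2),
           topo_signal = 0.5, seed = 42L) {
    key <- paste(n, prevalence, paste(signal, collapse = ","), topo_signal,
                 seed, sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_instance(synthetic_spec(
        n_nodes = n, prevalence = prevalence, signal = signal,
        topo_signal = topo_signal, seed = seed))
    }
    cache[[key]]
  }
})

# fast config for desk-scale training runs in tests
fast_config <- function(...) {
  dots <- list(...)
  tch <- list(epochs = 30L, n_teachers = 1L, patience = 1e9,
              ema_decay = 0.99)
  if (!is.null(dots$teacher)) {
    tch <- utils::modifyList(tch, dots$teacher)
    dots$teacher <- NULL
  }
  do.call(model_config, c(list(eval_every = 5L, teacher = tch), dots))
}
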