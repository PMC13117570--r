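test_that("structural metrics match closed forms on star, triangle, path", {
  s5 <- normalize_adjacency(star_graph(4))   # center + 4 leaves
  sf <- structural_features(s5)
  expect_equal(sf$metric_names,
               c("degree", "betweenness", "closeness", "eigenvector",
                 "clustering", "pagerank", "core"))
  expect_equal(sf$values[1, 1], 4)            # center degree
  expect_equal(sf$values[1, 2], 1.0)          # center normalized betweenness
  expect_equal(sf$values[2, 5], 0)            # leaf clustering

  k3 <- normalize_adjacency(triangle_graph())
  sk <- structural_features(k3)$values
  expect_equal(sk[, 5], rep(1, 3))            # clustering
  expect_equal(sk[, 1], rep(2, 3))            # degree
  expect_equal(sk[, 6], rep(1 / 3, 3))        # PageRank by symmetry

  p3 <- normalize_adjacency(path_graph(3))
  sp <- structural_features(p3)$values
  expect_equal(sp[, 7], rep(1, 3))            # core numbers
  expect_equal(sp[2, 2], 1.0)                 # middle betweenness (n = 3)
})

test_that("all seven metrics agree with brute force on random graphs", {
  set.seed(17)
  metric <- c("degree", "betweenness", "closeness", "eigenvector",
              "clustering", "pagerank", "core")
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    g <- normalize_adjacency(random_connected_graph(n, 0.3))
    got <- structural_features(g)$values
    want <- bf_structural(g)
    for (j in 1:7) {
      expect_lt(max(abs(got[, j] - want[, j])), 1e-6,
                label = paste("metric", metric[j]))
    }
    expect_lt(abs(sum(got[, 6]) - 1), 1e-8)   # PageRank sums to 1
  }
})

test_that("isolated nodes get zero for undefined centralities", {
  g <- normalize_adjacency(gene_graph(c("C", "L1", "L2", "L3", "ISO"),
                                      rbind(c(1, 2), c(1, 3), c(1, 4))))
  v <- structural_features(g)$values
  expect_equal(v[5, c(1, 2, 3, 5, 7)], rep(0, 5), ignore_attr = TRUE)
  expect_lt(v[5, 4], 1e-8)          # eigenvector mass stays on the star
  expect_lt(abs(sum(v[, 6]) - 1), 1e-8)
})

test_that("walks with p=q=1 step uniformly over neighbors", {
  # fixed 5-node graph where node 1 has exactly 3 neighbors
  g <- gene_graph(LETTERS[1:5],
                  rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(3, 5)))
  w <- node2vec_walks(g, p = 1, q = 1, walk_length = 50L,
                      walks_per_node = 250L, seed = 9)
  # collect the successor of every visit to node 1
  succ <- integer(0)
  for (r in seq_len(nrow(w))) {
    row <- w[r, ]
    at <- which(row[-length(row)] == 1L & !is.na(row[-1]))
    succ <- c(succ, row[at + 1L])
  }
  expect_gt(length(succ), 1e4)
  tab <- table(factor(succ, levels = c(2, 3, 4)))
  chi <- stats::chisq.test(tab, p = rep(1 / 3, 3))
  expect_gt(chi$p.value, 0.01)
})

test_that("large q suppresses outward steps on a path", {
  # path A-B-C-D: arriving at C from B, a q -> Inf walker cannot go to D
  g <- path_graph(4)
  w <- node2vec_walks(g, p = 1, q = 1e6, walk_length = 30L,
                      walks_per_node = 80L, seed = 4)
  n_out <- 0L; n_back <- 0L
  for (r in seq_len(nrow(w))) {
    row <- w[r, ]
    for (t in 2:(length(row) - 1)) {
      if (is.na(row[t + 1])) break
      if (row[t] == 3L && row[t - 1] == 2L) {     # at C, came from B
        if (row[t + 1] == 4L) n_out <- n_out + 1L else n_back <- n_back + 1L
      }
    }
  }
  expect_gt(n_back, 50L)
  expect_equal(n_out, 0L)
  # and the return bias: small p forces immediate backtracking
  w2 <- node2vec_walks(g, p = 1e-6, q = 1, walk_length = 20L,
                       walks_per_node = 30L, seed = 4)
  expect_true(all(w2[w2[, 1] == 2L, 3][!is.na(w2[w2[, 1] == 2L, 3])] == 2L))
})

test_that("embeddings are reproducible under a seed and non-degenerate", {
  set.seed(1)
  g <- normalize_adjacency(random_gene_graph(40, 0.15))
  e1 <- node2vec_embed(g, walk_length = 20L, walks_per_node = 4L,
                       dim = 8L, epochs = 1L, seed = 33)
  e2 <- node2vec_embed(g, walk_length = 20L, walks_per_node = 4L,
                       dim = 8L, epochs = 1L, seed = 33)
  expect_identical(e1$values, e2$values)
  connected <- which(Matrix::rowSums(g$adjacency) > 0)
  expect_true(all(apply(e1$values[connected, ], 1,
                        function(r) any(r != 0))))
})

test_that("enhancement bundle widths follow the toggles", {
  s <- matrix(1, 5, 7); wlk <- matrix(2, 5, 3); tl <- matrix(3, 5, 1)
  full <- enhancement_bundle(s, wlk, tl)
  expect_equal(ncol(full), 7 + 3 + 1)
  no_walk <- enhancement_bundle(s, wlk, tl, use_walks = FALSE)
  expect_equal(ncol(full) - ncol(no_walk), 3)
  expect_null(enhancement_bundle(use_structural = FALSE, use_walks = FALSE,
                                 use_teacher = FALSE))
  expect_error(enhancement_bundle(s, NULL, tl), "walk")
})

test_that("residual enhancement reduces to identity and to the MLP alone", {
  set.seed(2)
  H <- matrix(rnorm(20), 5, 4)
  Xe <- matrix(rnorm(15), 5, 3)
  zero <- list(W1 = matrix(0, 3, 4), b1 = matrix(0, 1, 4),
               W2 = matrix(0, 4, 4), b2 = matrix(0, 1, 4))
  expect_equal(enhance(H, Xe, zero), H)           # zeroed MLP: identity
  expect_equal(enhance(H, NULL), H)               # all toggles off
  pars <- drivergnn:::init_enhance_mlp(3L, 4L)
  mlp_only <- enhance(H * 0, Xe, pars)
  expect_equal(enhance(H, Xe, pars), H + mlp_only, tolerance = 1e-12)
})
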