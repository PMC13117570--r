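test_that("edge-list parsing deduplicates, drops self-edges, thresholds", {
  f <- withr::local_tempfile(lines = c("A B", "B A", "A A", "B C"))
  g <- read_edge_list(f)
  expect_equal(g$symbols, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(unname(g$edges), rbind(c(1L, 2L), c(2L, 3L)))

  f2 <- withr::local_tempfile(lines = c("A B 0.9", "B C 0.3"))
  g2 <- read_edge_list(f2, min_confidence = 0.5)
  expect_equal(g2$symbols, c("A", "B"))
  expect_equal(nrow(g2$edges), 1L)

  f3 <- withr::local_tempfile(lines = c("# comment", "a  b", " b\tc "))
  g3 <- read_edge_list(f3)
  expect_equal(g3$symbols, c("A", "B", "C"))

  f4 <- withr::local_tempfile(lines = c("A B", "C"))
  expect_error(read_edge_list(f4), "line 2")
  f5 <- withr::local_tempfile(lines = "A B 0.1")
  expect_error(read_edge_list(f5, min_confidence = 0.9), "empty graph")
})

test_that("parsing a random edge file matches a set-based recount", {
  set.seed(11)
  syms <- sprintf("GENE%02d", 1:50)
  a <- sample(syms, 200, replace = TRUE)
  b <- sample(syms, 200, replace = TRUE)
  f <- withr::local_tempfile(lines = paste(a, b, sep = "\t"))
  g <- read_edge_list(f)
  # independent line-by-line set count
  keys <- unique(ifelse(a < b, paste(a, b), paste(b, a))[a != b])
  nodes <- sort(unique(c(a, b)[rep(a != b, 2)]))
  expect_equal(length(g$symbols), length(nodes))
  expect_equal(nrow(g$edges), length(keys))
})

test_that("write/read round trip preserves nodes and edges", {
  set.seed(3)
  g <- normalize_adjacency(random_gene_graph(30, 0.15))
  f <- withr::local_tempfile()
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  expect_equal(g2$symbols, g$symbols)
  expect_equal(g2$edges, g$edges)
})

test_that("normalized adjacency matches closed forms on tiny graphs", {
  g1 <- normalize_adjacency(gene_graph("A", matrix(integer(0), 0, 2)))
  expect_equal(as.matrix(g1$norm_adjacency), matrix(1), ignore_attr = TRUE)

  g2 <- normalize_adjacency(gene_graph(c("A", "B"), cbind(1L, 2L)))
  expect_equal(as.matrix(g2$norm_adjacency), matrix(0.5, 2, 2),
               ignore_attr = TRUE)

  g3 <- normalize_adjacency(triangle_graph())
  expect_equal(as.matrix(g3$norm_adjacency), matrix(1 / 3, 3, 3),
               ignore_attr = TRUE)

  bad <- gene_graph(c("A", "B"), cbind(1L, 2L))
  bad$adjacency@x <- c(2, 2)
  expect_error(normalize_adjacency(bad), "binary")
})

test_that("normalized adjacency is symmetric and matches dense brute force", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    g <- normalize_adjacency(random_gene_graph(n, 0.2))
    M <- as.matrix(g$norm_adjacency)
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_lt(max(abs(M - dense_norm_adjacency(g$adjacency))), 1e-10)
  }
})

test_that("feature alignment reorders, zero-fills, and drops correctly", {
  g <- normalize_adjacency(path_graph(3))  # A-B-C
  tb <- data.frame(gene = c("C", "A", "B"),
                   matrix(seq_len(3 * 64), 3, 64))
  al <- align_features(g, tb) |> suppressMessages()
  expect_equal(al$omics$values[1, 1], tb[tb$gene == "A", 2])
  expect_equal(al$omics$values[3, 1], tb[tb$gene == "C", 2])

  tb2 <- tb[tb$gene != "B", ]
  al2 <- suppressMessages(align_features(g, tb2, missing_policy = "zero"))
  expect_true(all(al2$omics$values[2, ] == 0))
  expect_equal(length(al2$graph$symbols), 3L)

  # drop policy: induced subgraph must match a rebuild from filtered edges
  set.seed(5)
  g100 <- random_gene_graph(100, 0.06)
  feat <- data.frame(gene = g100$symbols, matrix(rnorm(100 * 64), 100, 64))
  missing <- sample(g100$symbols, 10)
  al3 <- suppressMessages(
    align_features(g100, feat[!feat$gene %in% missing, ], "drop"))
  expect_equal(length(al3$graph$symbols), 90L)
  keep_syms <- setdiff(g100$symbols, missing)
  e_sym <- cbind(g100$symbols[g100$edges[, 1]], g100$symbols[g100$edges[, 2]])
  surv <- e_sym[e_sym[, 1] %in% keep_syms & e_sym[, 2] %in% keep_syms, ,
                drop = FALSE]
  oracle <- gene_graph(sort(keep_syms),
                       cbind(match(surv[, 1], sort(keep_syms)),
                             match(surv[, 2], sort(keep_syms))))
  expect_equal(sort(al3$graph$symbols), oracle$symbols)
  expect_equal(nrow(al3$graph$edges), nrow(oracle$edges))

  feat_bad <- feat
  feat_bad$gene <- paste0("ENSG", seq_len(100))
  expect_error(suppressMessages(align_features(g100, feat_bad)), "mismatch")
})

test_that("standardizer uses population std, guards constants, and is fold-aware", {
  X <- matrix(0, 4, 64)
  X[, 1] <- c(1, 3, 10, 20)
  st <- fit_standardizer(X, rows = 1:2)
  expect_equal(st$means[1], 2)
  expect_equal(st$stds[1], 1)  # population std of {1,3}
  expect_equal(st$stds[2], 1)  # constant column guarded to 1
  Z <- apply_standardizer(X, st)
  expect_equal(Z[1:2, 1], c(-1, 1))
  expect_true(all(Z[1:2, 2] == 0))

  set.seed(8)
  X2 <- matrix(rnorm(20 * 64), 20, 64)
  rows <- 1:12
  Z2 <- apply_standardizer(X2, fit_standardizer(X2, rows))
  expect_lt(max(abs(colMeans(Z2[rows, ]))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(Z2[rows, ], 2,
                                        colMeans(Z2[rows, ]))^2)) - 1)),
            1e-6)

  st2 <- fit_standardizer(X2, rows)
  expect_length(intersect(st2$source_rows, 13:20), 0)

  om <- omics_matrix(X2)
  om_z <- apply_standardizer(om, st2)
  expect_true(om_z$standardized)
  expect_error(apply_standardizer(om_z, st2), "already standardized")
  expect_error(fit_standardizer(X2, integer(0)), "empty")

  # identity stats leave the matrix unchanged
  ident <- structure(list(means = rep(0, 64), stds = rep(1, 64),
                          source_rows = rows),
                     class = "standardization_stats")
  expect_equal(apply_standardizer(X2, ident), X2)
})

test_that("label sets partition the nodes and survive a file round trip", {
  ls <- label_set(10, positives = c(2, 5), negatives = c(1, 3))
  expect_length(intersect(ls$positives, ls$negatives), 0)
  expect_setequal(c(ls$positives, ls$negatives, ls$unlabeled), 1:10)
  expect_error(label_set(10, 1:3, 3:5), "overlap")

  g <- normalize_adjacency(path_graph(5))
  fp <- withr::local_tempfile(lines = c("B", "D"))
  fn <- withr::local_tempfile(lines = c("A", "ZZZ"))
  lab <- suppressMessages(read_labels(g, fp, fn))
  expect_equal(lab$positives, c(2L, 4L))
  expect_equal(lab$negatives, 1L)
  y <- label_vector(lab)
  expect_equal(y[2], 1)
  expect_true(is.na(y[3]))
})
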