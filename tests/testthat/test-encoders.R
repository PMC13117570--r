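# residual-GCN layer forward in plain matrices, for hand-check cases
layer_out <- function(H, adnorm, WL, Wc) {
  tape <- drivergnn:::ad_tape()
  ctx <- drivergnn:::fwd_ctx(list(l.WL = WL, l.Wc = Wc), tape)
  Hn <- drivergnn:::ad_const(tape, H)
  drivergnn:::residual_gcn_layer(ctx, "l", Hn, adnorm)$value
}

test_that("residual layer reduces to its two pure paths and the K3 closed form", {
  g <- normalize_adjacency(triangle_graph())
  A <- g$norm_adjacency
  set.seed(2)
  H <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(9), 3, 3)
  # W_c = 0: pure node-wise path
  expect_equal(layer_out(H, A, W, W * 0), pmax(H %*% W, 0))
  # W_L = 0: pure convolution path
  expect_equal(layer_out(H, A, W * 0, W),
               pmax(as.matrix(A %*% H) %*% W, 0))
  # K3, H = I, W_L = W_c = I: ReLU(I) + ReLU(J/3) = I + J/3
  I3 <- diag(3)
  expect_equal(layer_out(I3, A, I3, I3), I3 + matrix(1 / 3, 3, 3))
})

test_that("encoders are node-permutation equivariant and deterministic", {
  set.seed(12)
  n <- 10L
  g <- normalize_adjacency(random_gene_graph(n, 0.3))
  X <- matrix(rnorm(n * 16), n, 16)
  set.seed(77)
  enc <- drivergnn:::init_encoder(16L, 8L, 12L)
  run <- function(graph, Xb) {
    tape <- drivergnn:::ad_tape()
    ctx <- drivergnn:::fwd_ctx(drivergnn:::flatten_params(list(e = enc)), tape)
    drivergnn:::encoder_forward(ctx, "e", Xb, graph$norm_adjacency)$value
  }
  out1 <- run(g, X)
  expect_equal(run(g, X), out1)  # determinism
  perm <- sample(n)
  gp <- normalize_adjacency(gene_graph(
    g$symbols[perm], cbind(match(g$edges[, 1], perm),
                           match(g$edges[, 2], perm))))
  # node i of g sits at position match(i, perm) of gp
  out_p <- run(gp, X[perm, , drop = FALSE])
  expect_equal(out_p, out1[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("zero convolution weights make the encoder topology-independent", {
  set.seed(30)
  n <- 12L
  g1 <- normalize_adjacency(random_gene_graph(n, 0.3))
  g2 <- normalize_adjacency(random_gene_graph(n, 0.5))
  X <- matrix(rnorm(n * 16), n, 16)
  enc <- drivergnn:::init_encoder(16L, 8L, 12L)
  enc$l1$Wc[] <- 0
  enc$l2$Wc[] <- 0
  run <- function(g) {
    tape <- drivergnn:::ad_tape()
    ctx <- drivergnn:::fwd_ctx(drivergnn:::flatten_params(list(e = enc)), tape)
    drivergnn:::encoder_forward(ctx, "e", X, g$norm_adjacency)$value
  }
  expect_equal(run(g1), run(g2))
})

test_that("expression bank: zero view MLPs leave only the fuse bias", {
  set.seed(4)
  n <- 6L
  g <- normalize_adjacency(random_gene_graph(n, 0.5))
  cfg <- model_config(hidden1 = 4L, hidden2 = 5L, dropout = 0,
                      augment_enabled = FALSE,
                      active_blocks = "expression", fusion = "sum")
  params <- init_model_params(cfg, 0L)
  for (nm in grep("^mlp_e2", names(params), value = TRUE)) params[[nm]][] <- 0
  b <- rnorm(5)
  params[["expr_fuse.b"]][] <- b
  ops <- drivergnn:::graph_operators(g$adjacency, cfg)
  X <- matrix(rnorm(n * 64), n, 64)
  fw <- drivergnn:::model_forward(params, cfg, X, ops, NULL, FALSE)
  # heads consume it downstream; check the fused node directly via zero fuse W
  expect_true(is.null(fw$attention_weights))
  tape <- drivergnn:::ad_tape()
  ctx <- drivergnn:::fwd_ctx(params, tape)
  # rebuild just the expression branch to inspect H2
  outs <- lapply(c("e21", "e23", "e24"), function(v) {
    hv <- drivergnn:::encoder_forward(ctx, paste0("enc_", v),
                                      X[, 17:32], ops$adnorm)
    drivergnn:::mlp_forward(ctx, paste0("mlp_", v), hv, 2L)
  })
  cc <- drivergnn:::ad_concat_cols(outs, tape)
  H2 <- drivergnn:::ad_add_bias(
    drivergnn:::ad_matmul(cc, drivergnn:::pget(ctx, "expr_fuse.W"), tape),
    drivergnn:::pget(ctx, "expr_fuse.b"), tape)
  expect_equal(H2$value, matrix(b, n, 5L, byrow = TRUE), ignore_attr = TRUE)
})

test_that("permuting views together with fuse column blocks leaves H2 unchanged", {
  set.seed(9)
  n <- 5L
  g <- normalize_adjacency(random_gene_graph(n, 0.6))
  cfg <- model_config(hidden1 = 4L, hidden2 = 6L, dropout = 0,
                      augment_enabled = FALSE)
  params <- init_model_params(cfg, 0L)
  X <- matrix(rnorm(n * 64), n, 64)
  ops <- drivergnn:::graph_operators(g$adjacency, cfg)
  h2 <- function(pp) {
    tape <- drivergnn:::ad_tape()
    ctx <- drivergnn:::fwd_ctx(pp, tape)
    outs <- lapply(c("e21", "e23", "e24"), function(v) {
      hv <- drivergnn:::encoder_forward(ctx, paste0("enc_", v),
                                        X[, 17:32], ops$adnorm)
      drivergnn:::mlp_forward(ctx, paste0("mlp_", v), hv, 2L)
    })
    cc <- drivergnn:::ad_concat_cols(outs, tape)
    drivergnn:::ad_matmul(cc, drivergnn:::pget(ctx, "expr_fuse.W"),
                          tape)$value
  }
  base <- h2(params)
  # swap views e21 <-> e23 and the matching row blocks of the fuse matrix
  pp <- params
  for (suf in c("l1.WL", "l1.Wc", "l2.WL", "l2.Wc", "ln_gamma", "ln_beta")) {
    tmp <- pp[[paste0("enc_e21.", suf)]]
    pp[[paste0("enc_e21.", suf)]] <- pp[[paste0("enc_e23.", suf)]]
    pp[[paste0("enc_e23.", suf)]] <- tmp
  }
  for (suf in c("W1", "b1", "W2", "b2")) {
    tmp <- pp[[paste0("mlp_e21.", suf)]]
    pp[[paste0("mlp_e21.", suf)]] <- pp[[paste0("mlp_e23.", suf)]]
    pp[[paste0("mlp_e23.", suf)]] <- tmp
  }
  W <- params[["expr_fuse.W"]]
  d <- nrow(W) / 3
  pp[["expr_fuse.W"]] <- rbind(W[(d + 1):(2 * d), ], W[1:d, ],
                               W[(2 * d + 1):(3 * d), ])
  expect_equal(h2(pp), base, tolerance = 1e-12)
})

test_that("augmentation: identity at zero rates, binomial edge survival", {
  set.seed(14)
  g <- normalize_adjacency(random_gene_graph(40, 0.15))
  X <- matrix(rnorm(40 * 8), 40, 8)
  a0 <- augment(X, g, 0, 0)
  expect_equal(a0$X, X)
  expect_equal(as.matrix(a0$norm_adjacency), as.matrix(g$norm_adjacency))
  expect_error(augment(X, g, 1, 0), "rates")
  expect_error(augment(X, g, 0, 1.2), "rates")

  # binomial expectation of surviving edges
  m <- nrow(g$edges)
  set.seed(99)
  surv <- replicate(400, augment(X, g, 0, 0.3)$n_edges)
  expect_lt(abs(mean(surv) - 0.7 * m),
            3 * sqrt(m * 0.3 * 0.7 / 400) + 1e-9)
  # feature mask zeroes roughly the requested fraction
  set.seed(100)
  masked <- replicate(50, mean(augment(X, g, 0.25, 0)$X == 0))
  expect_lt(abs(mean(masked) - 0.25), 0.02)

  # reproducible under seed
  a1 <- augment(X, g, 0.2, 0.2, seed = 5)
  a2 <- augment(X, g, 0.2, 0.2, seed = 5)
  expect_equal(a1$X, a2$X)
  expect_equal(as.matrix(a1$norm_adjacency), as.matrix(a2$norm_adjacency))
})

test_that("dropped-edge counts follow the binomial law (chi-square)", {
  set.seed(200)
  g <- normalize_adjacency(random_gene_graph(30, 0.25))
  m <- nrow(g$edges)
  p <- 0.3
  drops <- replicate(600, m - augment(matrix(0, 30, 2), g, 0, p)$n_edges)
  br <- seq(-0.5, m + 0.5)
  obs <- tabulate(drops + 1L, nbins = m + 1L)
  expp <- stats::dbinom(0:m, m, p) * 600
  keep <- expp > 1
  chi <- sum((obs[keep] - expp[keep])^2 / expp[keep])
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})
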