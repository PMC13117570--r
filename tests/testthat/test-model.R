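# Training-loop behavior on small planted-signal instances.

test_that("training loss decreases over early epochs on planted signal", {
  inst <- tiny_instance(n = 100L, prevalence = 0.15, seed = 19L)
  y <- label_vector(inst$labels)
  X <- std_values(inst$omics, which(!is.na(y)))
  cfg <- model_config(hidden1 = 12L, hidden2 = 16L, d_a = 8L,
                      proj_dim = 12L, gcn_head_width = 12L,
                      gcn_head_depth = 3L, mlp_head_widths = c(12L, 8L, 6L),
                      lr = 0.005, augment_enabled = FALSE)
  set.seed(2)
  m <- train_model(inst$graph, X, y, which(!is.na(y)), cfg, epochs = 50L)
  sm <- stats::filter(m$history, rep(1 / 5, 5), sides = 1)
  expect_lt(min(sm, na.rm = TRUE), sm[5])            # smoothed improvement
  expect_lt(mean(m$history[41:50]), mean(m$history[1:10]))
})

test_that("zero learning rate freezes predictions", {
  inst <- tiny_instance(n = 60L, prevalence = 0.2, seed = 23L)
  y <- label_vector(inst$labels)
  X <- std_values(inst$omics, which(!is.na(y)))
  cfg <- model_config(hidden1 = 6L, hidden2 = 8L, d_a = 4L, proj_dim = 6L,
                      gcn_head_width = 6L, gcn_head_depth = 2L,
                      mlp_head_widths = c(6L, 4L, 3L),
                      augment_enabled = FALSE)
  set.seed(9)
  params0 <- init_model_params(cfg, 0L)
  set.seed(9)
  m <- train_model(inst$graph, X, y, which(!is.na(y)), cfg, epochs = 5L,
                   lr = 0, weight_decay = 0)
  expect_equal(m$params, params0, tolerance = 1e-12)
})

test_that("the deep GCN head keeps gradient flowing to its first layer", {
  inst <- tiny_instance(n = 80L, prevalence = 0.15, seed = 29L)
  y <- label_vector(inst$labels)
  X <- std_values(inst$omics, which(!is.na(y)))
  cfg <- model_config(hidden1 = 8L, hidden2 = 10L, d_a = 4L, proj_dim = 8L,
                      gcn_head_width = 10L, gcn_head_depth = 6L,
                      mlp_head_widths = c(8L, 6L, 4L), lr = 0.003,
                      augment_enabled = FALSE, dropout = 0)
  set.seed(3)
  idx <- which(!is.na(y))
  params <- init_model_params(cfg, 0L)
  state <- drivergnn:::adamw_state(params)
  ops <- drivergnn:::graph_operators(inst$graph$adjacency, cfg)
  w <- auto_class_weights(y[idx])
  g1 <- NA
  for (ep in 1:50) {
    fw <- drivergnn:::model_forward(params, cfg, X, ops, NULL, TRUE)
    lg <- as.numeric(fw$logits$value)
    gv <- matrix(0, length(y), 1)
    gv[idx, 1] <- drivergnn:::balanced_bce_grad(lg[idx], y[idx], w)
    grads <- drivergnn:::ad_backward(fw$tape, fw$logits, gv)
    if (ep == 50) g1 <- sqrt(sum(grads[["heads.gcn.l1.WL"]]^2))
    up <- drivergnn:::adamw_step(params, grads, state, cfg$lr,
                                 cfg$weight_decay)
    params <- up$params; state <- up$state
  }
  expect_gt(g1, 1e-8)
})

test_that("lambda 0 with teacher toggle off ignores teacher logits entirely", {
  inst <- tiny_instance(n = 60L, prevalence = 0.2, seed = 31L)
  y <- label_vector(inst$labels)
  X <- std_values(inst$omics, which(!is.na(y)))
  cfg <- model_config(hidden1 = 6L, hidden2 = 8L, d_a = 4L, proj_dim = 6L,
                      gcn_head_width = 6L, gcn_head_depth = 2L,
                      mlp_head_widths = c(6L, 4L, 3L), lambda_kd = 0,
                      use_teacher = FALSE, augment_enabled = FALSE)
  tl <- rnorm(60)
  set.seed(4)
  m1 <- train_model(inst$graph, X, y, which(!is.na(y)), cfg, epochs = 5L,
                    teacher_logits = tl)
  set.seed(4)
  m2 <- train_model(inst$graph, X, y, which(!is.na(y)), cfg, epochs = 5L,
                    teacher_logits = NULL)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
})

test_that("training aborts with a clear error on divergence", {
  inst <- tiny_instance(n = 50L, prevalence = 0.2, seed = 37L)
  y <- label_vector(inst$labels)
  X <- std_values(inst$omics, which(!is.na(y))) * 1e308  # force overflow
  cfg <- model_config(hidden1 = 4L, hidden2 = 6L, d_a = 3L, proj_dim = 4L,
                      gcn_head_width = 4L, gcn_head_depth = 2L,
                      mlp_head_widths = c(4L, 3L, 3L),
                      augment_enabled = FALSE)
  set.seed(5)
  expect_error(train_model(inst$graph, X, y, which(!is.na(y)), cfg,
                           epochs = 3L),
               "diverged|unlabeled")
})

test_that("train/validation overlap and unlabeled training nodes are refused", {
  inst <- tiny_instance(n = 50L, prevalence = 0.2, seed = 41L)
  y <- label_vector(inst$labels)
  y[1:5] <- NA
  X <- std_values(inst$omics, 6:50)
  cfg <- model_config(hidden1 = 4L, hidden2 = 6L, d_a = 3L, proj_dim = 4L,
                      gcn_head_width = 4L, gcn_head_depth = 2L,
                      mlp_head_widths = c(4L, 3L, 3L))
  expect_error(train_model(inst$graph, X, y, 1:20, cfg, epochs = 1L),
               "unlabeled")
  expect_error(train_model(inst$graph, X, y, 6:20, cfg, epochs = 1L,
                           val_idx = 20:25), "overlap")
})
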