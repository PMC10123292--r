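# Loss function, optimization, hyperparameter search, Y-scrambling.

test_that("multitask BCE matches hand computation and decomposes over tasks", {
  # single molecule, single task, pred 0.5, label 1 -> -log(0.5)
  expect_equal(multitask_bce_loss(matrix(0.5), matrix(1), matrix(TRUE)),
               -log(0.5), tolerance = 1e-12)
  # pred == label exactly -> loss 0 up to the clamping epsilon
  expect_lt(multitask_bce_loss(matrix(c(1, 0), 2, 1), matrix(c(1, 0), 2, 1),
                               matrix(TRUE, 2, 1)), 1e-6)
  # two tasks: total = (L1 + L2) / 2, against per-task recomputation
  set.seed(9)
  p <- matrix(runif(20), 10, 2)
  y <- matrix(rbinom(20, 1, 0.5), 10, 2)
  m <- matrix(runif(20) < 0.8, 10, 2)
  l1 <- multitask_bce_loss(p[, 1, drop = FALSE], y[, 1, drop = FALSE],
                           m[, 1, drop = FALSE])
  l2 <- multitask_bce_loss(p[, 2, drop = FALSE], y[, 2, drop = FALSE],
                           m[, 2, drop = FALSE])
  expect_equal(multitask_bce_loss(p, y, m), (l1 + l2) / 2, tolerance = 1e-12)
  # all-masked batch is a defined error, not NaN
  expect_error(multitask_bce_loss(p, y, matrix(FALSE, 10, 2)),
               class = "fpgnn_loss_error")
})

test_that("fully-masked molecules do not change the loss", {
  set.seed(11)
  p <- matrix(runif(10), 5, 2)
  y <- matrix(rbinom(10, 1, 0.5), 5, 2)
  m <- matrix(TRUE, 5, 2)
  base <- multitask_bce_loss(p, y, m)
  p2 <- rbind(p, matrix(runif(4), 2, 2))
  y2 <- rbind(y, matrix(1, 2, 2))
  m2 <- rbind(m, matrix(FALSE, 2, 2))
  expect_equal(multitask_bce_loss(p2, y2, m2), base, tolerance = 1e-15)
})

test_that("analytic gradients match finite differences on a small toy", {
  cfg <- model_config(n_tasks = 2, fpn_hidden = 5, gnn_hidden = 4,
                      gnn_depth = 2, gnn_heads = 2, readout_dim = 3,
                      fusion_hidden = 6, dropout = 0, seed = 7)
  m <- init_model(cfg)
  smis <- c("CCO", "O=[N+]([O-])c1ccccc1")
  FP <- fingerprint_matrix(smis)
  batch <- batch_graphs(lapply(smis, mol_to_graph))
  label <- matrix(c(1, 0, NA, 1), 2, 2)
  mask <- !is.na(label)

  fwd <- forward_batch(m, FP, batch)
  lg <- loss_and_grad(fwd$logits, label, mask)
  gv <- flatten_params(backward_batch(m, FP, batch, fwd, lg$dlogits))
  pv <- flatten_params(m$params)

  lossfun <- function(v) {
    mm <- m
    mm$params <- unflatten_params(m$params, v)
    f <- forward_batch(mm, FP, batch)
    loss_and_grad(f$logits, label, mask)$loss
  }
  eps <- 1e-6
  set.seed(13)
  idx <- sort(sample(length(pv), 150))
  for (i in idx) {
    v1 <- pv; v1[i] <- v1[i] + eps
    v2 <- pv; v2[i] <- v2[i] - eps
    num <- (lossfun(v1) - lossfun(v2)) / (2 * eps)
    rel <- abs(num - gv[i]) / max(1e-6, abs(num) + abs(gv[i]))
    expect_lt(rel, 1e-4)
  }
})

test_that("a tiny model learns the nitro substructure task to high AUC", {
  fit <- fx_nitro_fit()
  expect_lte(fit$best_epoch, 30)
  rep <- evaluate_model(fit, fx_nitro_split()$test)
  auc_test <- rep$auc[rep$task == "nitro"]
  expect_gte(auc_test, 0.95)
})

test_that("training is deterministic and respects patience", {
  sp <- cluster_split(fx_nitro_data()[1:120, ], k = 1, n_valid = 20,
                      n_test = 20, seed = 2)
  mcfg <- fx_tiny_mcfg(seed = 17)
  tcfg <- train_config(epochs = 4, batch_size = 32, lr = 5e-3,
                       patience = 4, seed = 19)
  f1 <- train_model(sp, mcfg, tcfg)
  f2 <- train_model(sp, mcfg, tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(flatten_params(f1$model$params),
                   flatten_params(f2$model$params))

  # patience = 0: stops at the first epoch without strict improvement
  tcfg0 <- train_config(epochs = 30, batch_size = 32, lr = 5e-3,
                        patience = 0, seed = 19)
  f3 <- train_model(sp, mcfg, tcfg0)
  h <- f3$history
  expect_lt(nrow(h), 30)
  expect_gte(f3$best_epoch, nrow(h) - 1)
  expect_equal(h$val_auc_avg[f3$best_epoch], max(h$val_auc_avg))

  # task-count mismatch is a loud error
  expect_error(train_model(sp, fx_tiny_mcfg(n_tasks = 3), tcfg),
               class = "fpgnn_shape_error")
})

test_that("hyperparameter search ranks configurations by validation AUC", {
  sp <- cluster_split(fx_nitro_data()[1:120, ], k = 1, n_valid = 20,
                      n_test = 20, seed = 2)
  space <- list(gnn_hidden = c(4, 8), fpn_hidden = c(8, 16))
  tcfg <- train_config(epochs = 2, batch_size = 32, lr = 5e-3,
                       patience = 2, seed = 23)
  res <- hyperparameter_search(sp, space, budget = 3, tcfg = tcfg, seed = 29)
  expect_equal(nrow(res$leaderboard), 3)
  expect_true(all(diff(res$leaderboard$val_auc) <= 0))
  expect_s3_class(res$best_config, "model_config")
  # reproducible
  res2 <- hyperparameter_search(sp, space, budget = 3, tcfg = tcfg, seed = 29)
  expect_identical(res$leaderboard, res2$leaderboard)
  # degenerate budget returns the single evaluated config
  res1 <- hyperparameter_search(sp, space, budget = 1, tcfg = tcfg, seed = 29)
  expect_equal(nrow(res1$leaderboard), 1)
  expect_error(hyperparameter_search(sp, list(), budget = 1, tcfg = tcfg),
               class = "fpgnn_parameter_error")
})

test_that("y_scramble validates inputs and preserves class balance", {
  expect_error(y_scramble(fx_nitro_split(), fx_tiny_mcfg(),
                          fx_tiny_tcfg(), rounds = 0),
               class = "fpgnn_parameter_error")
  d <- fx_nitro_data()
  scr <- scramble_labels(d, 77)
  expect_equal(sum(scr$nitro), sum(d$nitro))     # within-task permutation
  expect_false(identical(scr$nitro, d$nitro))
  expect_identical(is.na(scr$nitro), is.na(d$nitro))
})
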