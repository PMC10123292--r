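# Network structure: branch forward passes, fusion, prediction contracts,
# checkpointing.

test_that("fpn_forward respects shape contracts and determinism", {
  m <- fx_init_model()
  d_fp <- m$schema$d_fp
  # zero fingerprint through zero-bias layers -> zero embedding
  expect_equal(fpn_forward(numeric(d_fp), m),
               numeric(utils::tail(m$config$fpn_hidden, 1)))
  fp <- mixed_fingerprint("c1ccccc1C(=O)O")
  e1 <- fpn_forward(fp, m)
  e2 <- fpn_forward(fp, m)
  expect_identical(e1, e2)
  expect_length(e1, utils::tail(m$config$fpn_hidden, 1))
  err <- tryCatch(fpn_forward(numeric(10), m), error = identity)
  expect_s3_class(err, "fpgnn_shape_error")
  expect_match(conditionMessage(err), "10")
  expect_match(conditionMessage(err), as.character(d_fp))
})

test_that("gnn_forward attention normalizes and handles degenerate graphs", {
  m <- fx_init_model()
  g <- mol_to_graph("CC(=O)Nc1ccccc1")
  emb <- gnn_forward(g, m, capture_attention = TRUE)
  att <- attr(emb, "attention")
  sums <- att |>
    dplyr::group_by(.data$layer, .data$head, .data$dst) |>
    dplyr::summarise(s = sum(.data$coefficient), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(att$coefficient >= 0))

  # single heavy atom: runs, readout of the lone atom
  e1 <- gnn_forward(mol_to_graph("C"), m)
  expect_length(e1, m$config$gnn_hidden * m$config$gnn_heads)
  expect_true(all(is.finite(e1)))
})

test_that("whole-model forward is invariant to atom renumbering", {
  m <- fx_init_model()
  e1 <- gnn_forward(mol_to_graph("c1ccccc1CCO"), m)
  clear_mol_cache()
  e2 <- gnn_forward(mol_to_graph("OCCc1ccccc1"), m)
  expect_equal(e1, e2, tolerance = 1e-10)
  p1 <- predict_prob_matrix(m, "c1ccccc1CCO")
  clear_mol_cache()
  p2 <- predict_prob_matrix(m, "OCCc1ccccc1")
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("fuse_and_predict obeys the sigmoid contracts", {
  m <- fx_init_model()
  d_g <- m$config$gnn_hidden * m$config$gnn_heads
  d_f <- utils::tail(m$config$fpn_hidden, 1)
  # zero head weights force logits 0 -> probabilities exactly 0.5
  m0 <- m
  m0$params$head$W[] <- 0
  m0$params$head$b[] <- 0
  probs <- fuse_and_predict(rnorm(d_f), rnorm(d_g), m0)
  expect_equal(probs, rep(0.5, m$config$n_tasks))
  # T = 1 config -> length-1 output
  m1 <- init_model(model_config(n_tasks = 1, fpn_hidden = 4, gnn_hidden = 3,
                                gnn_depth = 1, gnn_heads = 1, readout_dim = 3,
                                fusion_hidden = 4, seed = 1))
  expect_length(fuse_and_predict(rnorm(4), rnorm(3), m1), 1)
  # probabilities stay inside (0, 1) for finite weights
  for (i in 1:20) {
    pr <- fuse_and_predict(rnorm(d_f, sd = 10), rnorm(d_g, sd = 10), m)
    expect_true(all(pr > 0 & pr < 1))
  }
})

test_that("predict applies the 0.5 tie-positive threshold in input order", {
  m <- fx_init_model()
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0
  out <- predict(m, c(a = "CCO", b = "c1ccccc1"))
  expect_tibble(out)
  expect_equal(nrow(out), 2 * m$config$n_tasks)
  expect_equal(unique(out$id), c("a", "b"))   # input order preserved
  # zero head -> probability exactly 0.5 -> call 1 under the >= convention
  expect_true(all(out$probability == 0.5))
  expect_true(all(out$call == 1))
  # threshold rule around 0.5
  expect_equal(as.integer(c(0.49, 0.51, 0.5) >= 0.5), c(0L, 1L, 1L))
  err <- tryCatch(predict(m, c(bad = "C1CC")), error = identity)
  expect_s3_class(err, "fpgnn_featurization_error")
  expect_match(conditionMessage(err), "bad")
})

test_that("task heads are separated: perturbing head j changes only task j", {
  m <- fx_init_model()
  smi <- "O=[N+]([O-])c1ccccc1"
  base <- predict_prob_matrix(m, smi)
  m2 <- m
  m2$params$head$W[, 2] <- m2$params$head$W[, 2] + 0.5
  pert <- predict_prob_matrix(m2, smi)
  expect_equal(pert[, 1], base[, 1])
  expect_false(isTRUE(all.equal(pert[, 2], base[, 2])))
})

test_that("checkpoints round-trip bit-exactly and validate their schema", {
  m <- fx_init_model()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  smi <- c("CCO", "Cc1ccc(cc1)S(=O)(=O)N")
  expect_identical(predict_prob_matrix(m, smi), predict_prob_matrix(m2, smi))

  # wrong expected config (different T) -> loud error naming the mismatch
  cfg_wrong <- model_config(n_tasks = 5, fpn_hidden = 8, gnn_hidden = 6,
                            gnn_depth = 2, gnn_heads = 2, readout_dim = 5,
                            fusion_hidden = 8, dropout = 0, seed = 42)
  err <- tryCatch(load_model(path, config = cfg_wrong), error = identity)
  expect_s3_class(err, "fpgnn_schema_error")
  expect_match(conditionMessage(err), "T=5")
  expect_match(conditionMessage(err), "T=2")

  expect_error(load_model(file.path(tempdir(), "absent.ckpt")),
               class = "fpgnn_io_error")
  garbage <- withr::local_tempfile(fileext = ".ckpt")
  saveRDS(list(1, 2), garbage)
  expect_error(load_model(garbage), class = "fpgnn_io_error")
})

test_that("parameter flattening round-trips the parameter tree", {
  m <- fx_init_model()
  v <- flatten_params(m$params)
  p2 <- unflatten_params(m$params, v)
  expect_identical(p2, m$params)
})
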