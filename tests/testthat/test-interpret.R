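# Attention maps and fingerprint-bit importances.

test_that("attention maps are normalized and respect molecular symmetry", {
  model <- fx_interp_fit()$model
  map <- attention_map("CC(=O)Nc1ccccc1", model)
  # raw directed coefficients sum to one over each neighbourhood
  sums <- map$raw |>
    dplyr::group_by(.data$layer, .data$head, .data$dst) |>
    dplyr::summarise(s = sum(.data$coefficient), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(map$bonds$score >= 0))
  expect_equal(nrow(map$bonds), mol_to_graph("CC(=O)Nc1ccccc1")$n_bonds)
  expect_true(all(map$atoms$score_norm >= 0 & map$atoms$score_norm <= 1))

  # benzene: all six carbons are feature-identical, so all six bond scores
  # coincide to numerical tolerance
  mb <- attention_map("c1ccccc1", model)
  expect_equal(nrow(mb$bonds), 6)
  expect_lt(diff(range(mb$bonds$score)), 1e-10)

  # single-atom molecule: empty bond map, defined atom map
  m1 <- attention_map("C", model)
  expect_equal(nrow(m1$bonds), 0)
  expect_equal(nrow(m1$atoms), 1)

  expect_error(attention_map("c1ccccc1", model, layer = 99),
               class = "fpgnn_parameter_error")
})

test_that("attention is stable under input atom renumbering", {
  model <- fx_interp_fit()$model
  m1 <- attention_map("c1ccccc1CCO", model)
  clear_mol_cache()
  m2 <- attention_map("OCCc1ccccc1", model)
  expect_equal(sort(m1$bonds$score), sort(m2$bonds$score), tolerance = 1e-10)
})

test_that("bit importances: zero branch gives zero, label bits rank high", {
  fit <- fx_interp_fit()
  data <- fx_interp_split()$test[1:40, ]

  # a model whose fingerprint branch is all zeros cannot react to occlusion
  m0 <- fit$model
  for (l in seq_along(m0$params$fpn)) {
    m0$params$fpn[[l]]$W[] <- 0
    m0$params$fpn[[l]]$b[] <- 0
  }
  bi0 <- bit_importance(m0, data, task = 1, top_n = 20)
  expect_true(all(bi0$importance == 0))

  # the label is determined by halogen presence: among the top-5 occlusion
  # bits of the trained model, at least one belongs to the label-defining
  # key set (bits occurring only in positive molecules)
  FP <- fingerprint_matrix(data$smiles_canonical)
  indicator <- label_defining_bits(data, 1)
  expect_gt(length(indicator), 0)
  bi <- bit_importance(fit, data, task = 1, top_n = 5)
  expect_true(any(bi$global_index %in% indicator))
  # scores nonincreasing, length contract
  expect_true(all(diff(bi$importance) <= 0))
  expect_equal(nrow(bi), 5)

  # bits absent from every molecule have importance exactly zero
  absent <- setdiff(seq_len(ncol(FP)), which(colSums(FP != 0) > 0))
  big <- bit_importance(fit, data, task = 1, top_n = 1362)
  expect_true(all(big$importance[big$global_index %in% absent] == 0))

  # invariant to dataset ordering
  bi_rev <- bit_importance(fit, data[rev(seq_len(nrow(data))), ],
                           task = 1, top_n = 5)
  expect_equal(bi$global_index, bi_rev$global_index)
  expect_equal(bi$importance, bi_rev$importance, tolerance = 1e-12)

  # top_n clipping warns
  expect_warning(bit_importance(fit, data[1:5, ], top_n = 5000), "clipped")

  # the gradient-times-input alternative runs and is nonnegative
  bg <- bit_importance(fit, data[1:10, ], task = 1, top_n = 5,
                       method = "grad_input")
  expect_true(all(bg$importance >= 0))
})

test_that("attention renderings are written and re-readable", {
  model <- fx_interp_fit()$model
  map <- attention_map("O=[N+]([O-])c1ccc(C)cc1", model)
  path <- withr::local_tempfile(fileext = ".png")
  render_molecule_attention(map, "O=[N+]([O-])c1ccc(C)cc1", path)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 1000)
  img <- png::readPNG(path)
  expect_gte(length(dim(img)), 2)
  # molecule/map mismatch is an error
  expect_error(render_molecule_attention(map, "CCO", path),
               class = "fpgnn_parameter_error")
})
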