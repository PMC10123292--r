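# Applicability domain: threshold fitting, classification, parameter grid.

test_that("fit_ad reproduces the 1-D hand computation", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  ad <- fit_ad(X, k = 1, Z = 0.5)
  expect_equal(ad$knn_mean, c(1, 1, 1, 8))
  expect_equal(ad$d_ave, 2.75)
  theta_pop <- sqrt(mean((c(1, 1, 1, 8) - 2.75)^2))
  expect_equal(ad$theta, theta_pop)
  expect_equal(ad$D_T, 2.75 + 0.5 * theta_pop)
  # Z = 0 -> threshold is exactly the mean
  expect_equal(fit_ad(X, k = 1, Z = 0)$D_T, 2.75)
  # identical training vectors -> all distances zero
  ad0 <- fit_ad(matrix(1, 5, 3), k = 2, Z = 3)
  expect_equal(ad0$d_ave, 0)
  expect_equal(ad0$theta, 0)
  expect_equal(ad0$D_T, 0)
  expect_error(fit_ad(X, k = 4), class = "fpgnn_parameter_error")
  expect_error(fit_ad(X, k = 0), class = "fpgnn_parameter_error")
})

test_that("classify_ad applies the nearest-neighbour threshold rule", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  ad <- fit_ad(X, k = 1, Z = 0.5)
  # query identical to a training compound -> distance 0 -> ID
  res <- classify_ad(matrix(2, 1, 1), ad)
  expect_equal(res$distance, 0)
  expect_equal(res$flag, "ID")
  # enormous Z admits everything
  ad_huge <- fit_ad(X, k = 1, Z = 1e6)
  far <- classify_ad(matrix(1e4, 1, 1), ad_huge)
  expect_equal(far$flag, "ID")
  # distance 9 against a threshold of 5 -> OD
  ad5 <- ad; ad5$D_T <- 5
  expect_equal(classify_ad(matrix(19, 1, 1), ad5)$flag, "OD")
  expect_error(classify_ad(matrix(1, 1, 3), ad), class = "fpgnn_shape_error")
})

test_that("AD quantities scale linearly and ignore training order", {
  set.seed(41)
  X <- matrix(runif(60), 20, 3)
  ad1 <- fit_ad(X, k = 3, Z = 0.7)
  c_scale <- 2.5
  ad2 <- fit_ad(X * c_scale, k = 3, Z = 0.7)
  expect_equal(ad2$d_ave, c_scale * ad1$d_ave, tolerance = 1e-12)
  expect_equal(ad2$theta, c_scale * ad1$theta, tolerance = 1e-12)
  expect_equal(ad2$D_T, c_scale * ad1$D_T, tolerance = 1e-12)
  Q <- matrix(runif(15), 5, 3)
  r1 <- classify_ad(Q, ad1)
  r2 <- classify_ad(Q * c_scale, ad2)
  expect_equal(r2$distance, c_scale * r1$distance, tolerance = 1e-12)
  expect_identical(r1$flag, r2$flag)
  # permutation invariance of the fitted threshold
  perm <- sample(nrow(X))
  ad3 <- fit_ad(X[perm, ], k = 3, Z = 0.7)
  expect_equal(ad3$D_T, ad1$D_T, tolerance = 1e-12)
  expect_equal(sort(ad3$knn_mean), sort(ad1$knn_mean), tolerance = 1e-12)
})

test_that("the OD probe set sits beyond the base set's neighbourhood scale", {
  spec <- synth_spec(n = 60, seed = 51)
  base <- generate_molecules(spec)
  probe <- generate_od_probe(synth_spec(n = 20, seed = 51), "phosphonate")
  # disjoint grammars -> no shared molecules
  expect_length(intersect(base$smiles_canonical, probe$smiles_canonical), 0)
  bf <- fingerprint_matrix(base$smiles_canonical)
  pf <- fingerprint_matrix(probe$smiles_canonical)
  ad <- fit_ad(bf, k = 3, Z = 0.2)
  cls <- classify_ad(pf, ad)
  expect_gt(mean(cls$distance), ad$d_ave)
  expect_gt(mean(cls$flag == "OD"), 0.5)
  expect_error(generate_od_probe(spec, ""), class = "fpgnn_parameter_error")
  expect_error(generate_od_probe(spec, "nosuch"), class = "fpgnn_parameter_error")
})

test_that("ad_grid covers the canonical point and is monotone in Z", {
  split <- fx_nitro_split()
  fit <- fx_nitro_fit()
  grid <- ad_grid(split, fit, k_values = c(1, 3), Z_values = c(0, 0.2, 0.5))
  expect_tibble(grid)
  expect_true(any(grid$k == 3 & grid$Z == 0.2))   # default operating point
  for (kk in unique(grid$k)) {
    sub <- grid[grid$k == kk, ]
    sub <- sub[order(sub$Z), ]
    expect_true(all(diff(sub$n_od) <= 0))
  }
  expect_equal(grid$n_id + grid$n_od, rep(nrow(split$test), nrow(grid)))
  p <- autoplot(grid)
  expect_s3_class(p, "ggplot")
})
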