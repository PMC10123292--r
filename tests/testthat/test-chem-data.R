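# Dataset reading, cleaning, splitting and profiling.

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_dataset maps labels, masks and drops malformed SMILES", {
  path <- write_csv_fixture(c("smiles,tox", "CCO,1", "CCN,0", "CCC,"))
  d <- read_dataset(path)
  expect_equal(nrow(d), 3)
  expect_equal(dataset_tasks(d), "tox")
  expect_equal(unname(d$tox), c(1, 0, NA))
  expect_equal(unname(mask_matrix(d)[, 1]), c(TRUE, TRUE, FALSE))

  # unclosed ring -> dropped with a warning
  path2 <- write_csv_fixture(c("smiles,tox", "CCO,1", "C1CC,0"))
  expect_warning(d2 <- read_dataset(path2), "unparsable")
  expect_equal(nrow(d2), 1)

  # five tasks, labels present only for tasks 1 and 4
  path3 <- write_csv_fixture(c("smiles,a,b,c,d,e", "CCO,1,,,0,"))
  d3 <- read_dataset(path3)
  expect_equal(unname(mask_matrix(d3)[1, ]), c(TRUE, FALSE, FALSE, TRUE, FALSE))

  # contract errors
  path4 <- write_csv_fixture(c("structure,a", "CCO,1"))
  expect_error(read_dataset(path4), class = "fpgnn_config_error")
  path5 <- write_csv_fixture(c("smiles,a", "C1CC,1"))
  expect_warning(expect_error(read_dataset(path5), class = "fpgnn_empty_dataset_error"))
})

test_that("clean_dataset applies the fragment, inorganic and dedup rules", {
  path <- write_csv_fixture(c(
    "smiles,tox",
    "CC(=O)O.[Na+],1",   # sodium salt -> acetic acid fragment
    "O=[Si]=O,1",        # no carbon -> removed
    "OCC,0",             # duplicate pair under canonicalization
    "CCO,0",
    "CCN,1"))
  d <- clean_dataset(read_dataset(path))
  counts <- attr(d, "cleaning_counts")
  expect_equal(unname(counts["inorganic_removed"]), 1)
  expect_equal(unname(counts["duplicates_merged"]), 1)
  expect_equal(nrow(d), 3)
  # the salt kept the organic fragment: canonical form of acetic acid
  expect_equal(d$smiles_canonical[1], canonical_smiles("CC(=O)O"))
  # no two records share a canonical SMILES
  expect_equal(anyDuplicated(d$smiles_canonical), 0)
  # idempotence
  d2 <- clean_dataset(d)
  expect_equal(d2$smiles_canonical, d$smiles_canonical)
  expect_equal(label_matrix(d2), label_matrix(d))
})

test_that("duplicate label conflicts become missing labels", {
  path <- write_csv_fixture(c("smiles,tox", "OCC,1", "CCO,0"))
  d <- clean_dataset(read_dataset(path))
  expect_equal(nrow(d), 1)
  expect_true(is.na(d$tox[1]))
})

test_that("cluster_split stratifies, separates families, and is reproducible", {
  fam <- fx_two_families()
  sp <- cluster_split(fam$data, k = 2, n_valid = 8, n_test = 8, seed = 3)
  # family purity of the 2-means clustering on fingerprints
  cl <- sp$meta$cluster
  tab <- table(cl, fam$family)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.9)
  # pairwise disjoint by canonical SMILES
  expect_length(intersect(sp$train$smiles_canonical,
                          sp$validation$smiles_canonical), 0)
  expect_length(intersect(sp$train$smiles_canonical,
                          sp$test$smiles_canonical), 0)
  expect_length(intersect(sp$validation$smiles_canonical,
                          sp$test$smiles_canonical), 0)
  expect_equal(nrow(sp$validation), 8)
  expect_equal(nrow(sp$test), 8)
  expect_equal(nrow(sp$train), 24)
  # bit-for-bit reproducibility
  sp2 <- cluster_split(fam$data, k = 2, n_valid = 8, n_test = 8, seed = 3)
  expect_identical(sp$meta$cluster, sp2$meta$cluster)
  expect_identical(sp$train$id, sp2$train$id)
  # k-means objective is nonincreasing in k for the returned solutions
  sp3 <- cluster_split(fam$data, k = 3, n_valid = 8, n_test = 8, seed = 3)
  expect_lte(sp3$meta$wss, sp$meta$wss + 1e-9)
  # degenerate k = 1 reduces to a seeded random split
  sp1 <- cluster_split(fam$data, k = 1, n_valid = 8, n_test = 8, seed = 3)
  expect_equal(sort(unique(sp1$meta$cluster)), 1)
  expect_equal(nrow(sp1$train), 24)
  # parameter errors
  expect_error(cluster_split(fam$data, k = 99, n_valid = 2, n_test = 2),
               class = "fpgnn_parameter_error")
  expect_error(cluster_split(fam$data, k = 2, n_valid = 30, n_test = 20),
               class = "fpgnn_parameter_error")
})

test_that("elbow_curve drops sharply at the planted cluster count", {
  fam <- fx_two_families()
  ec <- elbow_curve(fam$data, k_max = 4, seed = 2)
  expect_equal(ec$k, 1:4)
  # two well-separated families: large drop from k=1 to k=2, small after
  drop12 <- ec$wss[1] - ec$wss[2]
  drop23 <- ec$wss[2] - ec$wss[3]
  expect_gt(drop12, 3 * max(drop23, 0))
  # nonincreasing up to restart noise
  expect_true(all(diff(ec$wss) <= 1e-8))
  expect_error(elbow_curve(fam$data, k_max = 1), class = "fpgnn_parameter_error")
  p <- autoplot(ec)
  expect_s3_class(p, "ggplot")
})

test_that("split manifest round-trips through disk", {
  fam <- fx_two_families()
  sp <- cluster_split(fam$data, k = 2, n_valid = 6, n_test = 6, seed = 1)
  dir <- withr::local_tempdir()
  write_split(sp, dir)
  expect_true(file.exists(file.path(dir, "split.json")))
  tr <- read_dataset(file.path(dir, "train.csv"))
  expect_equal(nrow(tr), nrow(sp$train))
  meta <- jsonlite::read_json(file.path(dir, "split.json"), simplifyVector = TRUE)
  expect_equal(meta$k, 2)
})

test_that("profile_dataset computes MW, LogP and scaffold fraction", {
  methane <- tibble::tibble(id = "m", smiles = "C",
                            smiles_canonical = canonical_smiles("C"), y = 1)
  attr(methane, "fpgnn_tasks") <- "y"
  pr <- profile_dataset(methane)
  expect_equal(pr$molecules$mw, 16.04, tolerance = 1e-3)
  # acyclic molecules share the empty scaffold
  expect_equal(pr$molecules$scaffold, "")
  expect_equal(pr$scaffold_fraction, 1)

  # n molecules sharing one benzene scaffold -> fraction 1/n
  benz <- fx_two_families()$data[1:10, ]
  pr2 <- profile_dataset(benz)
  expect_equal(length(unique(pr2$molecules$scaffold)), 1)
  expect_equal(pr2$scaffold_fraction, 1 / 10)

  # pairwise distinct scaffolds -> fraction 1
  distinct <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccoc1")
  dd <- tibble::tibble(id = as.character(1:4), smiles = distinct,
                       smiles_canonical = canonical_smiles(distinct),
                       y = 1)
  attr(dd, "fpgnn_tasks") <- "y"
  expect_equal(profile_dataset(dd)$scaffold_fraction, 1)

  # scaffold assignment is invariant to SMILES atom ordering
  s1 <- murcko_scaffold("Cc1ccccc1CC")
  s2 <- murcko_scaffold("CCc1ccccc1C")
  expect_identical(s1, s2)
  expect_identical(s1, murcko_scaffold("c1ccccc1"))

  # per-task counts
  counts <- profile_dataset(fx_two_families()$data)$task_counts
  expect_equal(counts$positives, 20)
  expect_equal(counts$negatives, 20)
  expect_equal(counts$missing, 0)
})
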