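# Molecular graphs and mixed fingerprints.

test_that("mol_to_graph builds the heavy-atom graph with the fixed schema", {
  g1 <- mol_to_graph("C")
  expect_equal(g1$n_atoms, 1)
  expect_equal(g1$n_bonds, 0)

  g2 <- mol_to_graph("CCO")
  expect_equal(g2$n_atoms, 3)
  expect_equal(g2$n_bonds, 2)

  g3 <- mol_to_graph("c1ccccc1")
  expect_equal(g3$n_atoms, 6)
  expect_equal(g3$n_bonds, 6)
  expect_equal(sum(g3$atom_features[, "aromatic"]), 6)
  expect_equal(sum(g3$bond_features[, "aromatic"]), 6)

  sch <- graph_schema()
  expect_equal(ncol(g3$atom_features), sch$d_atom)
  expect_equal(ncol(g3$bond_features), sch$d_bond)
  # every bond references two distinct valid atoms
  expect_true(all(g3$bonds[, 1] != g3$bonds[, 2]))
  expect_true(all(g3$bonds >= 1 & g3$bonds <= g3$n_atoms))

  expect_error(mol_to_graph("C1CC"), class = "fpgnn_featurization_error")
})

test_that("featurization is invariant under atom renumbering and pure", {
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1C(=O)O", "OC(=O)c1ccccc1"),
                c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"))
  for (p in pairs) {
    f1 <- mixed_fingerprint(p[1])$concatenated
    f2 <- mixed_fingerprint(p[2])$concatenated
    expect_equal(f1, f2)
    g1 <- mol_to_graph(p[1])
    g2 <- mol_to_graph(p[2])
    expect_equal(g1$n_atoms, g2$n_atoms)
    expect_equal(g1$n_bonds, g2$n_bonds)
    expect_equal(colSums(g1$atom_features), colSums(g2$atom_features))
  }
  # purity: repeated calls give identical results
  expect_identical(mixed_fingerprint("CCO")$concatenated,
                   mixed_fingerprint("CCO")$concatenated)
})

test_that("MACCS keys agree bit-for-bit with the frozen independent reference", {
  ref <- fx_maccs_reference()
  for (i in seq_len(nrow(ref))) {
    ours <- which(mixed_fingerprint(ref$smiles[i])$maccs == 1)
    expect_identical(ours, ref$bits[[i]], label = ref$smiles[i])
  }
})

test_that("fingerprint blocks have the fixed lengths and value ranges", {
  fp <- mixed_fingerprint("Cc1ccc(cc1)S(=O)(=O)N")
  lens <- fingerprint_lengths()
  expect_length(fp$maccs, lens[["maccs"]])
  expect_length(fp$pubchem, lens[["pubchem"]])
  expect_length(fp$erg, lens[["erg"]])
  expect_length(fp$concatenated, sum(lens))
  expect_true(all(fp$maccs %in% c(0L, 1L)))
  expect_true(all(fp$pubchem %in% c(0L, 1L)))
  expect_true(all(fp$erg >= 0))
  # concatenation order is [MACCS | PubChem | ErG]
  expect_equal(fp$concatenated[seq_len(166)], as.numeric(fp$maccs))
  expect_equal(fp$concatenated[166 + seq_len(881)], as.numeric(fp$pubchem))
  expect_equal(fp$concatenated[1047 + seq_len(315)], fp$erg)
  # methane sets strictly fewer bits than benzene
  expect_lt(sum(mixed_fingerprint("C")$maccs),
            sum(mixed_fingerprint("c1ccccc1")$maccs))
})

test_that("PubChem-style keys follow the shipped rule table", {
  tab <- pubchem_key_table()
  fp <- mixed_fingerprint("O=[N+]([O-])c1ccccc1")$pubchem
  idx <- function(desc) tab$local_index[tab$description == desc]
  expect_equal(fp[idx("nitro group")], 1L)
  expect_equal(fp[idx(">= 1 N")], 1L)
  expect_equal(fp[idx("N-O bond")], 1L)
  expect_equal(fp[idx("benzene ring")], 1L)
  expect_equal(fp[idx(">= 1 S")], 0L)
  # unassigned slots stay zero
  unassigned <- setdiff(seq_len(881), tab$local_index)
  expect_true(all(fp[unassigned] == 0))
  # ring-count keys: naphthalene has >= 2 aromatic rings, benzene does not
  fp_naph <- mixed_fingerprint("c1ccc2ccccc2c1")$pubchem
  fp_benz <- mixed_fingerprint("c1ccccc1")$pubchem
  k2arom <- tab$local_index[tab$rule == "ring_count" &
                            tab$definition == "aromatic" & tab$threshold == 2]
  expect_equal(fp_naph[k2arom], 1L)
  expect_equal(fp_benz[k2arom], 0L)
})

test_that("ErG bins count property pairs at topological distances", {
  info <- erg_bit_info()
  expect_equal(nrow(info), 315)
  expect_equal(info$global_index, 1047 + seq_len(315))
  # para-phenylenediamine: two donor amines at topological distance 5
  fp <- mixed_fingerprint("Nc1ccc(N)cc1")$erg
  dd5 <- info$local_index[info$p1 == "Donor" & info$p2 == "Donor" &
                          info$distance == 5]
  expect_gte(fp[dd5], 1)
  # fuzz: neighbouring bins get the 0.3 increment
  dd4 <- info$local_index[info$p1 == "Donor" & info$p2 == "Donor" &
                          info$distance == 4]
  expect_gte(fp[dd4], 0.3)
  # a molecule with no negative centre has empty Negative-Negative bins
  neg <- info$local_index[info$p1 == "Negative" & info$p2 == "Negative"]
  expect_true(all(mixed_fingerprint("CCO")$erg[neg] == 0))
})

test_that("global bit indices resolve to family, local index and meaning", {
  bi <- fp_bit_info(c(35, 166 + 1, 166 + 881 + 1, 1362))
  expect_equal(bi$family, c("MACCS", "PubChem", "ErG", "ErG"))
  expect_equal(bi$local_index, c(35, 1, 1, 315))
  expect_error(fp_bit_info(0))
  expect_error(fp_bit_info(1363))
})
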