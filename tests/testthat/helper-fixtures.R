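# Shared fixtures, computed lazily once per test run and cached in an
# environment. Everything is generated in code from fixed seeds; the only
# stored fixture is the frozen reference fingerprint table.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# 20 diverse drug-like fixture molecules with a frozen MACCS reference
# computed by an independent fingerprint implementation.
fx_maccs_reference <- function() {
  fx("maccs_ref", function() {
    df <- utils::read.delim(test_path("fixtures", "maccs_reference.tsv"),
                            stringsAsFactors = FALSE)
    df$bits <- lapply(strsplit(df$on_bits, ","), as.integer)
    df
  })
}

# single-task dataset: label = presence of a nitro group, 500 molecules,
# no noise; split 350/50/100
fx_nitro_spec <- function() {
  synth_spec(n = 500,
             tasks = list(nitro = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]"),
             noise = 0, missing = 0, balance = 0.5, seed = 101)
}

fx_nitro_data <- function() {
  fx("nitro_data", function() generate_molecules(fx_nitro_spec()))
}

fx_nitro_split <- function() {
  fx("nitro_split", function() {
    cluster_split(fx_nitro_data(), k = 1, n_valid = 50, n_test = 100, seed = 7)
  })
}

fx_tiny_mcfg <- function(n_tasks = 1, seed = 3) {
  model_config(n_tasks = n_tasks, fpn_hidden = 32, gnn_hidden = 16,
               gnn_depth = 2, gnn_heads = 2, readout_dim = 16,
               fusion_hidden = 32, dropout = 0.1, seed = seed)
}

fx_tiny_tcfg <- function(epochs = 30, seed = 5) {
  train_config(epochs = epochs, batch_size = 64, lr = 5e-3,
               patience = epochs, seed = seed)
}

# trained nitro model, shared by the learning, scrambling, AD and
# interpretation tests
fx_nitro_fit <- function() {
  fx("nitro_fit", function() {
    train_model(fx_nitro_split(), fx_tiny_mcfg(), fx_tiny_tcfg())
  })
}

# interpretation-study fixture: label = halogen presence with 15% label
# noise. The halogen substructure has a minimal contextual footprint, so
# its defining fingerprint keys are the label's sole determinants and the
# trained model's probabilities stay calibrated (not saturated) — the
# conditions under which single-bit occlusion is informative.
fx_interp_spec <- function() {
  synth_spec(n = 400, tasks = list(halogen = "[Cl,Br,I]"),
             noise = 0.15, missing = 0, balance = 0.5, seed = 103)
}

fx_interp_fit <- function() {
  fx("interp_fit", function() {
    sp <- fx_interp_split()
    train_model(sp, fx_tiny_mcfg(), train_config(epochs = 20, batch_size = 64,
                                                 lr = 5e-3, patience = 20,
                                                 seed = 5))
  })
}

fx_interp_split <- function() {
  fx("interp_split", function() {
    cluster_split(generate_molecules(fx_interp_spec()), k = 1,
                  n_valid = 60, n_test = 80, seed = 7)
  })
}

# bits that appear only in positive-label molecules of `data` (and in at
# least 3 of them): the label-defining key set for an occlusion check
label_defining_bits <- function(data, task) {
  FP <- fingerprint_matrix(data$smiles_canonical)
  y <- label_matrix(data)[, task]
  which(vapply(seq_len(ncol(FP)), function(b) {
    on <- FP[, b] != 0
    sum(on) >= 3 && all(y[on] == 1)
  }, logical(1)))
}

# an untrained but initialized tiny two-task model for structural tests
fx_init_model <- function() {
  fx("init_model", function() {
    init_model(model_config(n_tasks = 2, fpn_hidden = 8, gnn_hidden = 6,
                            gnn_depth = 2, gnn_heads = 2, readout_dim = 5,
                            fusion_hidden = 8, dropout = 0, seed = 42))
  })
}

# small two-family set for cluster purity checks: benzenes vs aliphatic amines
fx_two_families <- function() {
  benzenes <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
                "CC(C)c1ccccc1", "Oc1ccccc1", "COc1ccccc1", "Nc1ccccc1",
                "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1", "Cc1ccc(C)cc1",
                "Cc1ccccc1C", "Cc1cccc(C)c1", "Cc1ccc(O)cc1",
                "COc1ccc(C)cc1", "OCc1ccccc1", "ClCc1ccccc1",
                "CCc1ccc(C)cc1", "Nc1ccc(C)cc1")
  amines <- c("CCN", "CCCN", "CCCCN", "CCCCCN", "CNC", "CCNC", "CCCNC",
              "CCCCNC", "CCNCC", "CCCNCC", "CN(C)C", "CCN(C)C",
              "CCCN(C)C", "NCCN", "NCCCN", "NCCCCN", "CNCCN", "CNCCCN",
              "CCNCCN", "CN(C)CCN")
  data <- tibble::tibble(
    id = sprintf("fam_%02d", seq_len(40)),
    smiles = c(benzenes, amines),
    smiles_canonical = canonical_smiles(c(benzenes, amines)),
    activity = rep(c(1, 0), each = 20)
  )
  attr(data, "fpgnn_tasks") <- "activity"
  list(data = data, family = rep(c("benzene", "amine"), each = 20))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
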