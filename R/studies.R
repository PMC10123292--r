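# Study harnesses: reusable experimental designs built from the package's
# primitives, used by the validation suite and the reproduction script.

#' Multi-task benefit study on a low-data task
#'
#' Generates a two-task dataset whose tasks share a latent substructure
#' (via the generator's correlation knob), restricts the training labels of
#' the second task to `n_low` molecules, and compares the test AUC of a
#' multi-task model (both tasks) with a single-task model (low-data task
#' only), over seeded repeats. Parameter sharing lets the rich task teach
#' the shared substructure to the starved task.
#'
#' @param n_low Number of training labels kept for the low-data task.
#' @param repeats Number of seeded repeats.
#' @param seed Top-level seed.
#' @param n Dataset size per repeat.
#' @param epochs Training epochs per model.
#' @return A tibble with one row per repeat: `auc_multi`, `auc_single`
#'   (test AUC on the low-data task), and the repeat's seed.
#' @export
multitask_benefit_study <- function(n_low = 50, repeats = 5, seed = 1,
                                    n = 400, epochs = 15) {
  purrr::map_dfr(seq_len(repeats), function(r) {
    spec <- synth_spec(
      n = n,
      tasks = list(rich = "[SX4](=[OX1])(=[OX1])[NX3]",
                   low = "[CX3](=[OX1])[OX2H1]"),
      correlation = 0.6, balance = 0.5,
      seed = derive_seed(seed, "benefit-data", r))
    data <- generate_molecules(spec)
    split <- cluster_split(data, k = 1, n_valid = 50, n_test = 80,
                           seed = derive_seed(seed, "benefit-split", r))

    # starve the low-data task in the training set
    labelled <- which(!is.na(split$train$low))
    keep <- with_seed(derive_seed(seed, "benefit-mask", r), {
      sample(labelled, min(n_low, length(labelled)))
    })
    split$train$low[setdiff(labelled, keep)] <- NA_real_

    tcfg <- train_config(epochs = epochs, batch_size = 64, lr = 5e-3,
                         patience = epochs,
                         seed = derive_seed(seed, "benefit-train", r))
    mcfg_multi <- model_config(n_tasks = 2, fpn_hidden = 32, gnn_hidden = 16,
                               gnn_depth = 2, gnn_heads = 2, readout_dim = 16,
                               fusion_hidden = 32, dropout = 0.1,
                               seed = derive_seed(seed, "benefit-model", r))
    fit_multi <- train_model(split, mcfg_multi, tcfg)

    single <- split
    keep_cols <- c("id", "smiles", "smiles_canonical", "low")
    for (part in c("train", "validation", "test")) {
      single[[part]] <- single[[part]][, keep_cols]
      attr(single[[part]], "fpgnn_tasks") <- "low"
    }
    mcfg_single <- mcfg_multi
    mcfg_single$n_tasks <- 1L
    fit_single <- train_model(single, mcfg_single, tcfg)

    rep_multi <- evaluate_model(fit_multi, split$test)
    rep_single <- evaluate_model(fit_single, single$test)
    tibble::tibble(
      repeat_id = r,
      auc_multi = rep_multi$auc[rep_multi$task == "low"],
      auc_single = rep_single$auc[rep_single$task == "low"]
    )
  })
}
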