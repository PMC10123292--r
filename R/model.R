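# Model configuration and state for the fingerprint + graph-attention
# network (FP-GNN): a fingerprint ANN branch, an attentive message-passing
# branch over the molecular graph, fully connected fusion layers, and a
# parameter-sharing multi-task sigmoid head.

#' Model configuration
#'
#' All architecture hyperparameters of the FP-GNN network. Parameter shapes
#' are fully determined by this object plus the (fixed) featurization schema.
#'
#' @param n_tasks Number of prediction tasks T (>= 1).
#' @param fpn_hidden Integer vector of hidden sizes of the fingerprint
#'   branch; the last entry is the fingerprint embedding size.
#' @param gnn_hidden Per-head hidden size of each graph attention layer.
#' @param gnn_depth Number of message-passing layers (>= 1).
#' @param gnn_heads Number of attention heads per layer (>= 1, concatenated).
#' @param readout_dim Hidden size of the attention readout scorer.
#' @param fusion_hidden Integer vector of hidden sizes of the fusion trunk
#'   shared by all tasks.
#' @param dropout Dropout rate in `[0, 1)`, applied to fingerprint-branch and
#'   fusion-trunk activations during training only.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_tasks = 1, fpn_hidden = 64, gnn_hidden = 32,
                         gnn_depth = 2, gnn_heads = 2, readout_dim = 32,
                         fusion_hidden = 64, dropout = 0.1, seed = 1) {
  stopifnot(n_tasks >= 1, all(fpn_hidden >= 1), gnn_hidden >= 1,
            gnn_depth >= 1, gnn_heads >= 1, readout_dim >= 1,
            all(fusion_hidden >= 1), dropout >= 0, dropout < 1)
  structure(
    list(n_tasks = as.integer(n_tasks),
         fpn_hidden = as.integer(fpn_hidden),
         gnn_hidden = as.integer(gnn_hidden),
         gnn_depth = as.integer(gnn_depth),
         gnn_heads = as.integer(gnn_heads),
         readout_dim = as.integer(readout_dim),
         fusion_hidden = as.integer(fusion_hidden),
         dropout = dropout, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> T=", x$n_tasks,
      " fpn=[", paste(x$fpn_hidden, collapse = ","), "]",
      " gnn=", x$gnn_depth, "x", x$gnn_hidden, "x", x$gnn_heads, "h",
      " fusion=[", paste(x$fusion_hidden, collapse = ","), "]",
      " dropout=", x$dropout, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' Creates a full `fpgnn_model` (the model state): every learnable parameter
#' of the fingerprint branch, graph-attention branch, readout, fusion trunk
#' and per-task output heads, shaped by the configuration and the fixed
#' featurization schema, initialized with seeded Glorot-uniform weights.
#'
#' @param config A [model_config()].
#' @return An object of class `fpgnn_model`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  sch <- graph_schema()
  d_fp <- sum(fingerprint_lengths())
  with_seed(derive_seed(config$seed, "init"), {
    # fingerprint branch
    fpn <- list()
    d_in <- d_fp
    for (h in config$fpn_hidden) {
      fpn[[length(fpn) + 1]] <- list(W = glorot(d_in, h), b = numeric(h))
      d_in <- h
    }
    # graph branch
    gnn <- list()
    d_g <- sch$d_atom
    for (l in seq_len(config$gnn_depth)) {
      heads <- list()
      for (hh in seq_len(config$gnn_heads)) {
        dh <- config$gnn_hidden
        heads[[hh]] <- list(
          W = glorot(d_g, dh), b = numeric(dh),
          Wb = glorot(sch$d_bond, dh),
          a_dst = stats::runif(dh, -0.1, 0.1),
          a_src = stats::runif(dh, -0.1, 0.1)
        )
      }
      gnn[[l]] <- heads
      d_g <- config$gnn_hidden * config$gnn_heads
    }
    readout <- list(
      U = glorot(d_g, config$readout_dim), bu = numeric(config$readout_dim),
      w = stats::runif(config$readout_dim, -0.1, 0.1)
    )
    # fusion trunk + per-task heads (columns of W_out)
    fusion <- list()
    d_in <- d_g + utils::tail(config$fpn_hidden, 1)
    for (h in config$fusion_hidden) {
      fusion[[length(fusion) + 1]] <- list(W = glorot(d_in, h), b = numeric(h))
      d_in <- h
    }
    head <- list(W = glorot(d_in, config$n_tasks), b = numeric(config$n_tasks))

    structure(
      list(
        config = config,
        schema = list(d_fp = d_fp, d_atom = sch$d_atom, d_bond = sch$d_bond,
                      hash = schema_hash(c(sch$hash, d_fp))),
        params = list(fpn = fpn, gnn = gnn, readout = readout,
                      fusion = fusion, head = head),
        meta = list(epoch = 0L, best_val_auc = NA_real_)
      ),
      class = "fpgnn_model"
    )
  })
}

#' @export
print.fpgnn_model <- function(x, ...) {
  np <- length(flatten_params(x$params))
  cat("<fpgnn_model> ", np, " parameters, T=", x$config$n_tasks,
      ", schema ", x$schema$hash,
      if (!is.na(x$meta$best_val_auc))
        paste0(", best val AUC ", signif(x$meta$best_val_auc, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

# flatten/unflatten parameter trees for the optimizer and checks
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

unflatten_params <- function(template, v) {
  pos <- 0
  rebuild <- function(x) {
    if (is.list(x)) {
      lapply(x, rebuild)
    } else {
      n <- length(x)
      out <- v[(pos + 1):(pos + n)]
      pos <<- pos + n
      if (is.matrix(x)) dim(out) <- dim(x)
      out
    }
  }
  rebuild(template)
}

#' Save / load a model checkpoint
#'
#' The checkpoint archive holds every parameter tensor bit-exactly, the
#' configuration that shaped them, the featurization schema hash, and
#' training metadata. Loading verifies the schema hash against the installed
#' featurization schema and (optionally) an expected configuration, and fails
#' loudly on mismatch.
#'
#' @param model A `fpgnn_model`.
#' @param path Checkpoint file path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the restored
#'   `fpgnn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fpgnn_model"))
  saveRDS(list(format = "fpgnn-checkpoint-v1", model = model), path)
  invisible(path)
}

#' @param config Optional [model_config()]; if supplied, the checkpoint's
#'   configuration must match it exactly.
#' @rdname save_model
#' @export
load_model <- function(path, config = NULL) {
  if (!file.exists(path)) {
    abort_fpgnn(paste0("checkpoint file not found: ", path), "fpgnn_io_error")
  }
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "fpgnn-checkpoint-v1") ||
      !inherits(obj$model, "fpgnn_model")) {
    abort_fpgnn(paste0("not a valid fpgnn checkpoint: ", path), "fpgnn_io_error")
  }
  model <- obj$model
  sch <- graph_schema()
  current_hash <- schema_hash(c(sch$hash, sum(fingerprint_lengths())))
  if (!identical(model$schema$hash, current_hash)) {
    abort_fpgnn(sprintf(
      "checkpoint featurization schema %s does not match installed schema %s",
      model$schema$hash, current_hash), "fpgnn_schema_error")
  }
  if (!is.null(config)) {
    if (!identical(unclass(config), unclass(model$config))) {
      abort_fpgnn(sprintf(
        "checkpoint config mismatch: expected T=%d, found T=%d (full configs differ)",
        config$n_tasks, model$config$n_tasks), "fpgnn_schema_error")
    }
  }
  model
}
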