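# Forward and backward passes of the FP-GNN network, written as vectorized
# matrix operations over a batched (disjoint-union) molecular graph.
# Gradients are derived by hand and guarded by a finite-difference test.

# ---------------------------------------------------------------------------
# forward

# The fingerprint branch compresses the real-valued ErG count block with
# log1p so that count features enter on a scale comparable to the binary
# substructure keys; the binary blocks are unchanged. This is part of the
# model architecture, not of the fingerprint definition (AD distances use
# the raw vectors).
transform_fp_input <- function(FP) {
  lens <- fingerprint_lengths()
  if (ncol(FP) == sum(lens)) {
    erg_cols <- (lens[["maccs"]] + lens[["pubchem"]] + 1):sum(lens)
    FP[, erg_cols] <- log1p(FP[, erg_cols])
  }
  FP
}

forward_fpn <- function(fpn, FP, dropout = 0, training = FALSE) {
  layers <- list()
  A <- transform_fp_input(FP)
  for (l in seq_along(fpn)) {
    pre <- sweep(A %*% fpn[[l]]$W, 2, fpn[[l]]$b, "+")
    act <- relu(pre)
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(act), 1, 1 - dropout) / (1 - dropout),
                     nrow(act), ncol(act))
      act <- act * mask
    }
    layers[[l]] <- list(input = A, pre = pre, act = act, mask = mask)
    A <- act
  }
  list(layers = layers, emb = A)
}

forward_gnn_layer <- function(heads, H, batch) {
  outs <- vector("list", length(heads))
  caches <- vector("list", length(heads))
  for (hh in seq_along(heads)) {
    p <- heads[[hh]]
    Z <- sweep(H %*% p$W, 2, p$b, "+")
    P <- batch$EF %*% p$Wb
    msg <- Z[batch$src, , drop = FALSE] + P
    zvec <- as.vector(Z %*% p$a_dst)
    svec <- as.vector(msg %*% p$a_src)
    u_pre <- zvec[batch$dst] + svec
    u <- lrelu(u_pre)
    alpha <- segment_softmax(u, batch$dst, batch$dst_idx, batch$n_atoms)
    agg <- segment_sum(alpha * msg, batch$dst, batch$n_atoms)
    out <- relu(agg)
    outs[[hh]] <- out
    caches[[hh]] <- list(Z = Z, msg = msg, u_pre = u_pre, alpha = alpha, agg = agg)
  }
  list(out = do.call(cbind, outs), caches = caches)
}

forward_readout <- function(readout, H, batch) {
  t_act <- tanh(sweep(H %*% readout$U, 2, readout$bu, "+"))
  s <- as.vector(t_act %*% readout$w)
  beta <- segment_softmax(s, batch$mol_of_atom, batch$mol_idx, batch$n_mols)
  g <- segment_sum(beta * H, batch$mol_of_atom, batch$n_mols)
  list(t = t_act, s = s, beta = beta, g = g)
}

forward_gnn <- function(params, batch) {
  H <- batch$X
  layer_caches <- vector("list", length(params$gnn))
  H_inputs <- vector("list", length(params$gnn))
  for (l in seq_along(params$gnn)) {
    H_inputs[[l]] <- H
    fl <- forward_gnn_layer(params$gnn[[l]], H, batch)
    layer_caches[[l]] <- fl$caches
    H <- fl$out
  }
  read <- forward_readout(params$readout, H, batch)
  list(layers = layer_caches, H_inputs = H_inputs, H_final = H, read = read)
}

forward_fusion <- function(fusion, head, G, FPemb, dropout = 0, training = FALSE) {
  C <- cbind(G, FPemb)
  layers <- list()
  A <- C
  for (l in seq_along(fusion)) {
    pre <- sweep(A %*% fusion[[l]]$W, 2, fusion[[l]]$b, "+")
    act <- relu(pre)
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(act), 1, 1 - dropout) / (1 - dropout),
                     nrow(act), ncol(act))
      act <- act * mask
    }
    layers[[l]] <- list(input = A, pre = pre, act = act, mask = mask)
    A <- act
  }
  logits <- sweep(A %*% head$W, 2, head$b, "+")
  list(C = C, layers = layers, trunk = A, logits = logits)
}

# Full forward pass over a prepared batch (fingerprint matrix + graph batch).
forward_batch <- function(model, FP, batch, training = FALSE) {
  p <- model$params
  drop <- if (training) model$config$dropout else 0
  fpn <- forward_fpn(p$fpn, FP, drop, training)
  gnn <- forward_gnn(p, batch)
  fus <- forward_fusion(p$fusion, p$head, gnn$read$g, fpn$emb, drop, training)
  list(fpn = fpn, gnn = gnn, fusion = fus,
       logits = fus$logits, probs = sigmoid(fus$logits))
}

# ---------------------------------------------------------------------------
# loss

#' Masked multi-task binary cross-entropy loss
#'
#' Computes, for each task, the mean binary cross-entropy over the molecules
#' whose label is present for that task, then averages over tasks with at
#' least one labelled molecule. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param pred `n x T` matrix of predicted probabilities.
#' @param label `n x T` matrix of 0/1 labels (entries under a FALSE mask are
#'   ignored and may be NA).
#' @param mask `n x T` logical matrix; TRUE where a label is present.
#' @return The scalar loss.
#' @examples
#' multitask_bce_loss(matrix(0.5), matrix(1), matrix(TRUE))  # -log(0.5)
#' @export
multitask_bce_loss <- function(pred, label, mask) {
  stopifnot(all(dim(pred) == dim(label)), all(dim(pred) == dim(mask)))
  mask <- mask & !is.na(label)
  if (!any(mask)) {
    abort_fpgnn("loss undefined: every entry of the batch is masked out",
                "fpgnn_loss_error")
  }
  p <- clamp_prob(pred)
  task_losses <- vapply(seq_len(ncol(pred)), function(t) {
    m <- mask[, t]
    if (!any(m)) return(NA_real_)
    y <- label[m, t]
    -mean(y * log(p[m, t]) + (1 - y) * log(1 - p[m, t]))
  }, numeric(1))
  mean(task_losses, na.rm = TRUE)
}

# loss + gradient wrt logits (clamp treated as identity in the backward pass)
loss_and_grad <- function(logits, label, mask) {
  probs <- sigmoid(logits)
  mask <- mask & !is.na(label)
  loss <- multitask_bce_loss(probs, label, mask)
  active <- colSums(mask) > 0
  n_active <- sum(active)
  d <- matrix(0, nrow(logits), ncol(logits))
  for (t in which(active)) {
    m <- mask[, t]
    d[m, t] <- (probs[m, t] - label[m, t]) / (sum(m) * n_active)
  }
  list(loss = loss, dlogits = d, probs = probs)
}

# ---------------------------------------------------------------------------
# backward

backward_fpn <- function(fpn, cache, dEmb) {
  grads <- vector("list", length(fpn))
  dA <- dEmb
  for (l in rev(seq_along(fpn))) {
    cc <- cache$layers[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dPre <- dA * (cc$pre > 0)
    grads[[l]] <- list(W = crossprod(cc$input, dPre), b = colSums(dPre))
    dA <- tcrossprod(dPre, fpn[[l]]$W)
  }
  list(grads = grads, dInput = dA)
}

backward_fusion <- function(fusion, head, cache, dLogits, d_gnn) {
  gW_head <- crossprod(cache$trunk, dLogits)
  gb_head <- colSums(dLogits)
  dA <- tcrossprod(dLogits, head$W)
  grads <- vector("list", length(fusion))
  for (l in rev(seq_along(fusion))) {
    cc <- cache$layers[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dPre <- dA * (cc$pre > 0)
    grads[[l]] <- list(W = crossprod(cc$input, dPre), b = colSums(dPre))
    dA <- tcrossprod(dPre, fusion[[l]]$W)
  }
  list(grads = grads, head = list(W = gW_head, b = gb_head),
       dG = dA[, seq_len(ncol(d_gnn)), drop = FALSE],
       dFp = dA[, -seq_len(ncol(d_gnn)), drop = FALSE])
}

backward_readout <- function(readout, cache, batch, H, dG) {
  read <- cache
  mol <- batch$mol_of_atom
  dBeta <- rowSums(dG[mol, , drop = FALSE] * H)
  dH <- read$beta * dG[mol, , drop = FALSE]
  corr <- segment_sum(read$beta * dBeta, mol, batch$n_mols)
  ds <- read$beta * (dBeta - corr[mol])
  dt <- outer(ds, readout$w)
  dPre <- dt * (1 - read$t^2)
  gU <- crossprod(H, dPre)
  gbu <- colSums(dPre)
  gw <- as.vector(crossprod(read$t, ds))
  dH <- dH + tcrossprod(dPre, readout$U)
  list(grads = list(U = gU, bu = gbu, w = gw), dH = dH)
}

backward_gnn_layer <- function(heads, caches, H, batch, dOut) {
  dh <- ncol(caches[[1]]$Z)
  dH_prev <- matrix(0, nrow(H), ncol(H))
  grads <- vector("list", length(heads))
  for (hh in seq_along(heads)) {
    p <- heads[[hh]]
    cc <- caches[[hh]]
    cols <- ((hh - 1) * dh + 1):(hh * dh)
    dOut_h <- dOut[, cols, drop = FALSE]
    dAgg <- dOut_h * (cc$agg > 0)
    dAgg_e <- dAgg[batch$dst, , drop = FALSE]
    dAlpha <- rowSums(dAgg_e * cc$msg)
    dMsg <- cc$alpha * dAgg_e
    corr <- segment_sum(cc$alpha * dAlpha, batch$dst, batch$n_atoms)
    dU <- cc$alpha * (dAlpha - corr[batch$dst])
    dU <- dU * ifelse(cc$u_pre > 0, 1, 0.2)
    # u = (Z a_dst)[dst] + msg a_src
    dzvec <- segment_sum(dU, batch$dst, batch$n_atoms)
    dZ <- outer(dzvec, p$a_dst)
    ga_dst <- as.vector(crossprod(cc$Z, dzvec))
    dMsg <- dMsg + outer(dU, p$a_src)
    ga_src <- as.vector(crossprod(cc$msg, dU))
    # msg = Z[src] + EF Wb
    dZ <- dZ + segment_sum(dMsg, batch$src, batch$n_atoms)
    gWb <- crossprod(batch$EF, dMsg)
    gW <- crossprod(H, dZ)
    gb <- colSums(dZ)
    dH_prev <- dH_prev + tcrossprod(dZ, p$W)
    grads[[hh]] <- list(W = gW, b = gb, Wb = gWb, a_dst = ga_dst, a_src = ga_src)
  }
  list(grads = grads, dH = dH_prev)
}

# Full backward pass; returns gradients in the same tree shape as params.
backward_batch <- function(model, FP, batch, fwd, dLogits) {
  p <- model$params
  bf <- backward_fusion(p$fusion, p$head, fwd$fusion, dLogits, fwd$gnn$read$g)
  bfp <- backward_fpn(p$fpn, fwd$fpn, bf$dFp)
  br <- backward_readout(p$readout, fwd$gnn$read, batch, fwd$gnn$H_final, bf$dG)
  dH <- br$dH
  gnn_grads <- vector("list", length(p$gnn))
  for (l in rev(seq_along(p$gnn))) {
    bl <- backward_gnn_layer(p$gnn[[l]], fwd$gnn$layers[[l]],
                             fwd$gnn$H_inputs[[l]], batch, dH)
    gnn_grads[[l]] <- bl$grads
    dH <- bl$dH
  }
  list(fpn = bfp$grads, gnn = gnn_grads, readout = br$grads,
       fusion = bf$grads, head = bf$head)
}

# ---------------------------------------------------------------------------
# public branch-level operations (evaluation mode)

check_fp_length <- function(fp, model) {
  v <- if (inherits(fp, "mixed_fp")) fp$concatenated else as.numeric(fp)
  if (length(v) != model$schema$d_fp) {
    abort_fpgnn(sprintf(
      "fingerprint length %d does not match the model's schema length %d",
      length(v), model$schema$d_fp), "fpgnn_shape_error")
  }
  v
}

#' Fingerprint-branch forward pass
#'
#' Runs the fingerprint ANN branch in evaluation mode (no dropout) and
#' returns the fingerprint embedding.
#'
#' @param fp A [mixed_fingerprint()] object or a numeric vector of the
#'   schema's fingerprint length.
#' @param model A `fpgnn_model`.
#' @return Numeric embedding vector (length = last fingerprint hidden size).
#' @export
fpn_forward <- function(fp, model) {
  stopifnot(inherits(model, "fpgnn_model"))
  v <- check_fp_length(fp, model)
  as.vector(forward_fpn(model$params$fpn, matrix(v, 1))$emb)
}

#' Graph-branch forward pass
#'
#' Runs the attentive message-passing branch and molecule-level attention
#' readout in evaluation mode, returning the molecule embedding. Attention
#' coefficients of every layer/head are attached as the `attention`
#' attribute when `capture_attention = TRUE`.
#'
#' @param graph A [mol_to_graph()] object.
#' @param model A `fpgnn_model`.
#' @param capture_attention Capture per-edge attention coefficients?
#' @return Numeric embedding vector; optionally with an `attention`
#'   attribute (a tibble of layer, head, src, dst, coefficient).
#' @export
gnn_forward <- function(graph, model, capture_attention = FALSE) {
  stopifnot(inherits(model, "fpgnn_model"), inherits(graph, "mol_graph"))
  if (graph$n_atoms == 0) {
    abort_fpgnn("cannot run the graph branch on an empty graph",
                "fpgnn_shape_error")
  }
  batch <- batch_graphs(list(graph))
  fwd <- forward_gnn(model$params, batch)
  emb <- as.vector(fwd$read$g)
  if (capture_attention) {
    att <- purrr::map_dfr(seq_along(fwd$layers), function(l) {
      purrr::map_dfr(seq_along(fwd$layers[[l]]), function(hh) {
        tibble::tibble(layer = l, head = hh, src = batch$src, dst = batch$dst,
                       coefficient = fwd$layers[[l]][[hh]]$alpha)
      })
    })
    attr(emb, "attention") <- att
  }
  emb
}

#' Fuse branch embeddings and predict task probabilities
#'
#' Applies the shared fusion trunk and the per-task output heads to a pair of
#' branch embeddings (evaluation mode).
#'
#' @param fpn_emb Fingerprint-branch embedding from [fpn_forward()].
#' @param gnn_emb Graph-branch embedding from [gnn_forward()].
#' @param model A `fpgnn_model`.
#' @return Numeric vector of T probabilities in `[0, 1]`.
#' @export
fuse_and_predict <- function(fpn_emb, gnn_emb, model) {
  stopifnot(inherits(model, "fpgnn_model"))
  fus <- forward_fusion(model$params$fusion, model$params$head,
                        matrix(gnn_emb, 1), matrix(fpn_emb, 1))
  as.vector(sigmoid(fus$logits))
}

#' Predict inhibition probabilities for molecules
#'
#' Composes featurization, both branches and the fusion head. Deterministic
#' in evaluation mode. Calls use the 0.5 threshold with ties called positive.
#'
#' @param object A `fpgnn_model`.
#' @param newdata Character vector of SMILES, or a molecule dataset tibble.
#' @param ... Unused.
#' @return A tibble with one row per molecule and task: `id`, `smiles`,
#'   `task`, `probability`, `call` (1 iff probability >= 0.5).
#' @export
predict.fpgnn_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    data <- tibble::tibble(id = names(newdata) %||% sprintf("mol_%04d", seq_along(newdata)),
                           smiles = unname(newdata),
                           smiles_canonical = canonical_smiles(newdata))
    if (anyNA(data$smiles_canonical)) {
      bad <- data$id[is.na(data$smiles_canonical)]
      abort_fpgnn(paste0("unparsable SMILES for molecule(s): ",
                         paste(bad, collapse = ", ")),
                  "fpgnn_featurization_error")
    }
  } else {
    data <- newdata
  }
  probs <- predict_prob_matrix(object, data$smiles_canonical)
  tasks <- colnames(probs)
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(id = data$id, smiles = data$smiles),
                     tibble::as_tibble(probs)),
    cols = dplyr::all_of(tasks), names_to = "task", values_to = "probability")
  out$call <- as.integer(out$probability >= 0.5)
  out
}

# n x T probability matrix for a vector of (parsable) SMILES
predict_prob_matrix <- function(model, smiles, task_names = NULL) {
  FP <- fingerprint_matrix(smiles)
  graphs <- lapply(smiles, mol_to_graph)
  batch <- batch_graphs(graphs)
  fwd <- forward_batch(model, FP, batch, training = FALSE)
  probs <- fwd$probs
  colnames(probs) <- task_names %||% paste0("task_", seq_len(ncol(probs)))
  probs
}
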