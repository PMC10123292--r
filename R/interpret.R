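# Model interpretation: per-bond attention maps from the graph branch and
# ranked fingerprint-bit importances from the fingerprint branch.

#' Attention map for one molecule
#'
#' Captures the graph-attention coefficients during a forward pass. The raw
#' directed coefficients over each atom's neighbourhood sum to one (per
#' layer/head); heads are aggregated by mean, the symmetric bond score is
#' the mean of the two directed coefficients, and the per-atom aggregate is
#' the sum of incident bond scores, min-max normalized over the molecule for
#' rendering (raw values retained).
#'
#' @param smiles A single SMILES string.
#' @param model A `fpgnn_model`.
#' @param layer Which message-passing layer to read (default: last).
#' @param aggregation Head aggregation rule; only `"mean"` is defined.
#' @return An object of class `attention_map`: list with `bonds` (tibble
#'   `i`, `j`, `score`), `atoms` (tibble `atom`, `score`, `score_norm`),
#'   `raw` (directed coefficients of all layers/heads), `layer`, and the
#'   molecule's canonical SMILES and depiction coordinates.
#' @export
attention_map <- function(smiles, model, layer = model$config$gnn_depth,
                          aggregation = "mean") {
  stopifnot(inherits(model, "fpgnn_model"))
  aggregation <- match.arg(aggregation, "mean")
  if (layer < 1 || layer > model$config$gnn_depth) {
    abort_fpgnn(sprintf("layer %d out of range 1..%d", layer,
                        model$config$gnn_depth), "fpgnn_parameter_error")
  }
  graph <- mol_to_graph(smiles)
  emb <- gnn_forward(graph, model, capture_attention = TRUE)
  att <- attr(emb, "attention")
  sel <- att[att$layer == layer & att$src != att$dst, , drop = FALSE]

  if (nrow(sel) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer(), score = numeric())
    atoms <- tibble::tibble(atom = seq_len(graph$n_atoms), score = 0,
                            score_norm = 0)
  } else {
    sel$lo <- pmin(sel$src, sel$dst)
    sel$hi <- pmax(sel$src, sel$dst)
    bonds <- sel |>
      dplyr::group_by(.data$lo, .data$hi) |>
      dplyr::summarise(score = mean(.data$coefficient), .groups = "drop") |>
      dplyr::rename(i = "lo", j = "hi")
    atom_score <- numeric(graph$n_atoms)
    for (r in seq_len(nrow(bonds))) {
      atom_score[bonds$i[r]] <- atom_score[bonds$i[r]] + bonds$score[r]
      atom_score[bonds$j[r]] <- atom_score[bonds$j[r]] + bonds$score[r]
    }
    rng <- range(atom_score)
    norm <- if (diff(rng) > 0) (atom_score - rng[1]) / diff(rng) else
      rep(1, length(atom_score))
    atoms <- tibble::tibble(atom = seq_len(graph$n_atoms),
                            score = atom_score, score_norm = norm)
  }
  structure(
    list(bonds = bonds, atoms = atoms, raw = att, layer = layer,
         smiles_canonical = graph$smiles_canonical, coords = graph$coords,
         graph = graph),
    class = "attention_map"
  )
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> ", x$smiles_canonical, ", layer ", x$layer, ": ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Fingerprint-bit importances by occlusion
#'
#' Importance of bit b for a task = the mean absolute change in that task's
#' predicted probability when column b of the fingerprint is zeroed
#' (occlusion), averaged over the dataset. Bits that are zero across the
#' whole dataset have importance exactly 0. A gradient-times-input
#' alternative is available; both are deterministic.
#'
#' @param model A `fpgnn_model` (or `fpgnn_fit`).
#' @param data A molecule dataset tibble.
#' @param task Task index in 1..T.
#' @param top_n Number of top bits to return (clipped to the fingerprint
#'   length with a warning).
#' @param method `"occlusion"` (default) or `"grad_input"`.
#' @return A tibble of class `bit_importance`: `rank`, `importance`,
#'   `global_index`, `family`, `local_index`, `meaning`, sorted by
#'   decreasing importance.
#' @export
bit_importance <- function(model, data, task = 1, top_n = 10,
                           method = c("occlusion", "grad_input")) {
  if (inherits(model, "fpgnn_fit")) model <- model$model
  stopifnot(inherits(model, "fpgnn_model"), nrow(data) >= 1)
  method <- match.arg(method)
  if (task < 1 || task > model$config$n_tasks) {
    abort_fpgnn(sprintf("task %d out of range 1..%d", task, model$config$n_tasks),
                "fpgnn_parameter_error")
  }
  d_fp <- model$schema$d_fp
  if (top_n > d_fp) {
    warning("top_n clipped to the fingerprint length ", d_fp, call. = FALSE)
    top_n <- d_fp
  }
  FP <- fingerprint_matrix(data$smiles_canonical)
  graphs <- lapply(data$smiles_canonical, mol_to_graph)
  batch <- batch_graphs(graphs)
  gnn <- forward_gnn(model$params, batch)
  G <- gnn$read$g

  imp <- numeric(d_fp)
  present <- which(colSums(FP != 0) > 0)
  if (method == "occlusion") {
    base <- fusion_probs(model, G, FP)[, task]
    for (b in present) {
      FPb <- FP
      FPb[, b] <- 0
      imp[b] <- mean(abs(fusion_probs(model, G, FPb)[, task] - base))
    }
  } else {
    # gradient x input: d prob_task / d FP via the analytic backward pass
    p <- model$params
    fpn <- forward_fpn(p$fpn, FP)
    fus <- forward_fusion(p$fusion, p$head, G, fpn$emb)
    probs <- sigmoid(fus$logits)
    dLogits <- matrix(0, nrow(FP), model$config$n_tasks)
    dLogits[, task] <- probs[, task] * (1 - probs[, task])
    bf <- backward_fusion(p$fusion, p$head, fus, dLogits, G)
    bfp <- backward_fpn(p$fpn, fpn, bf$dFp)
    imp <- colMeans(abs(bfp$dInput * FP))
  }

  ord <- order(imp, decreasing = TRUE)[seq_len(top_n)]
  out <- dplyr::bind_cols(
    tibble::tibble(rank = seq_len(top_n), importance = imp[ord]),
    fp_bit_info(ord)
  )
  class(out) <- c("bit_importance", class(out))
  out
}

# probabilities from cached graph embeddings + a fingerprint matrix
fusion_probs <- function(model, G, FP) {
  fpn <- forward_fpn(model$params$fpn, FP)
  fus <- forward_fusion(model$params$fusion, model$params$head, G, fpn$emb)
  sigmoid(fus$logits)
}

#' Render a molecule with attention shading
#'
#' Draws the 2-D depiction with bonds shaded monotonically in their
#' symmetric attention score (darker = higher) and atoms sized by their
#' normalized aggregate. The layout comes from the deterministic 2-D
#' coordinates of the structure backend.
#'
#' @param map An [attention_map()].
#' @param smiles The molecule's SMILES; must canonicalize to the same
#'   molecule the map was computed from.
#' @param path Output image path (`.png`); its directory must exist.
#' @param width,height,dpi Device size in inches and resolution.
#' @return `path`, invisibly. The ggplot object is attached as the `plot`
#'   attribute.
#' @export
render_molecule_attention <- function(map, smiles, path,
                                      width = 5, height = 4, dpi = 150) {
  stopifnot(inherits(map, "attention_map"))
  can <- canonical_smiles(smiles)
  if (is.na(can) || !identical(can, map$smiles_canonical)) {
    abort_fpgnn("SMILES does not match the molecule of the attention map",
                "fpgnn_parameter_error")
  }
  p <- autoplot.attention_map(map)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  out <- invisible(path)
  attr(out, "plot") <- p
  out
}

#' @rdname render_molecule_attention
#' @param object An `attention_map`.
#' @param ... Unused.
#' @method autoplot attention_map
#' @export
autoplot.attention_map <- function(object, ...) {
  xy <- object$coords
  atoms <- object$atoms
  df_atoms <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    element = object$graph$elements,
    score_norm = atoms$score_norm
  )
  p <- ggplot2::ggplot()
  if (nrow(object$bonds) > 0) {
    df_bonds <- tibble::tibble(
      x = xy[object$bonds$i, 1], y = xy[object$bonds$i, 2],
      xend = xy[object$bonds$j, 1], yend = xy[object$bonds$j, 2],
      score = object$bonds$score
    )
    p <- p + ggplot2::geom_segment(
      data = df_bonds,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$score,
                   colour = .data$score)) +
      ggplot2::scale_colour_gradient(low = "grey80", high = "grey10",
                                     name = "bond attention") +
      ggplot2::scale_linewidth(range = c(0.5, 2.5), guide = "none")
  }
  p +
    ggplot2::geom_point(data = df_atoms,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$score_norm),
                        colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_text(data = df_atoms,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$element), size = 3) +
    ggplot2::scale_size(range = c(2, 8), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$smiles_canonical)
}
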