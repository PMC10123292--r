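# autoplot() methods for the package's result types.

#' Plot an elbow curve
#'
#' @param object An `elbow_curve` tibble from [elbow_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elbow_curve
#' @export
autoplot.elbow_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "k (clusters)", y = "within-cluster sum of squares",
                  title = "Elbow curve for structure-based splitting") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object A `fpgnn_fit` from [train_model()].
#' @param ... Unused.
#' @return A ggplot object with training loss and averaged validation AUC
#'   per epoch.
#' @method autoplot fpgnn_fit
#' @export
autoplot.fpgnn_fit <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_loss, series = "training loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_auc_avg, series = "validation AUC (avg)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot a per-task metrics report
#'
#' @param object A `metrics_report` from [evaluate_multitask()].
#' @param ... Unused.
#' @return A ggplot bar chart of AUC, F1, BA and MCC per task.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("task", "auc", "f1", "ba", "mcc")],
    cols = c("auc", "f1", "ba", "mcc"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-task evaluation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an applicability-domain grid
#'
#' @param object An `ad_grid` tibble from [ad_grid()].
#' @param ... Unused.
#' @return A ggplot object: inside- vs outside-domain averaged AUC across
#'   the (k, Z) grid, with the OD count as point size.
#' @method autoplot ad_grid
#' @export
autoplot.ad_grid <- function(object, ...) {
  df <- tidyr::pivot_longer(object, cols = c("auc_id", "auc_od"),
                            names_to = "subset", values_to = "auc")
  df$subset <- ifelse(df$subset == "auc_id", "inside domain", "outside domain")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Z, y = .data$auc,
                                   colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_od)) +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "averaged AUC", title = "Applicability-domain grid") +
    ggplot2::theme_minimal()
}

#' Plot Y-scrambling results
#'
#' @param object A `y_scramble_result` from [y_scramble()].
#' @param ... Unused.
#' @return A ggplot object comparing scrambled-round AUCs with the
#'   unscrambled reference.
#' @method autoplot y_scramble_result
#' @export
autoplot.y_scramble_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$round, y = .data$auc_avg,
                                       colour = .data$scrambled)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "firebrick",
                                            "TRUE" = "grey40"),
                                 labels = c("reference", "scrambled"),
                                 name = NULL) +
    ggplot2::labs(x = "round (0 = true labels)", y = "averaged test AUC",
                  title = "Y-scrambling validation") +
    ggplot2::theme_minimal()
}
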