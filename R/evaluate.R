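# Classification metrics: confusion counts at the 0.5 threshold, F1, MCC,
# balanced accuracy, sensitivity/specificity, and threshold-free AUC
# (Mann-Whitney with ties counted 0.5), per task and macro-averaged.

#' Confusion counts at a probability threshold
#'
#' Counts true/false positives/negatives over the masked-in entries, calling
#' positive iff probability >= `threshold` (ties positive).
#'
#' @param pred_prob Numeric vector of predicted probabilities.
#' @param label 0/1 labels.
#' @param mask Logical vector; only TRUE entries are counted. Default: all.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(pred_prob, label, mask = rep(TRUE, length(label)),
                      threshold = 0.5) {
  stopifnot(length(pred_prob) == length(label), length(label) == length(mask))
  mask <- mask & !is.na(label)
  if (!any(mask)) {
    abort_fpgnn("confusion counts undefined: no labelled entries under the mask",
                "fpgnn_metric_error")
  }
  call <- pred_prob[mask] >= threshold
  y <- label[mask] == 1
  structure(
    list(tp = sum(call & y), tn = sum(!call & !y),
         fp = sum(call & !y), fn = sum(!call & y)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " TN=", x$tn, " FP=", x$fp,
      " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' `f1()` is 2TP / (2TP + FN + FP); `mcc()` is the Matthews correlation
#' coefficient with the zero-denominator convention MCC = 0;
#' `sensitivity()` = TP / (TP + FN); `specificity()` = TN / (TN + FP);
#' `balanced_accuracy()` = (SE + SP) / 2. F1 with an empty denominator
#' (no positive calls and no positive labels) is undefined and returned
#' as NA.
#'
#' @param c A `confusion_counts` object.
#' @return A single numeric value.
#' @export
f1 <- function(c) {
  denom <- 2 * c$tp + c$fn + c$fp
  if (denom == 0) return(NA_real_)
  2 * c$tp / denom
}

#' @rdname f1
#' @export
mcc <- function(c) {
  denom2 <- (c$tp + c$fn) * (c$tp + c$fp) * (c$tn + c$fn) * (c$tn + c$fp)
  if (denom2 == 0) return(0)
  (c$tp * c$tn - c$fn * c$fp) / sqrt(denom2)
}

#' @rdname f1
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) return(NA_real_)
  c$tp / (c$tp + c$fn)
}

#' @rdname f1
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0) return(NA_real_)
  c$tn / (c$tn + c$fp)
}

#' @rdname f1
#' @export
balanced_accuracy <- function(c) {
  se <- sensitivity(c); sp <- specificity(c)
  if (is.na(se) || is.na(sp)) return(NA_real_)
  (se + sp) / 2
}

#' Area under the ROC curve
#'
#' Threshold-free AUC equal to the Mann-Whitney pair statistic: the fraction
#' of positive-negative pairs ranked concordantly, with ties counted 0.5.
#' Computed from midranks, so it is exact for any tie structure.
#'
#' @param pred_prob Numeric vector of scores.
#' @param label 0/1 labels.
#' @param mask Logical vector; only TRUE entries enter. Default: all.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(pred_prob, label, mask = rep(TRUE, length(label))) {
  stopifnot(length(pred_prob) == length(label), length(label) == length(mask))
  mask <- mask & !is.na(label)
  s <- pred_prob[mask]; y <- label[mask] == 1
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort_fpgnn(paste0("AUC undefined: no ",
                       if (n_pos == 0) "positive" else "negative",
                       " labels under the mask"), "fpgnn_metric_error")
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-task and averaged evaluation report
#'
#' Evaluates an `n x T` probability matrix against labels and masks:
#' confusion counts at the 0.5 threshold, F1, MCC, balanced accuracy,
#' sensitivity, specificity and AUC per task, plus unweighted macro averages
#' over the tasks where each metric is defined. Tasks failing a metric's
#' precondition (e.g. single-class labels for AUC) get NA for that metric,
#' are excluded from its average, and trigger a warning.
#'
#' @param preds `n x T` probability matrix.
#' @param labels `n x T` 0/1 label matrix (NA allowed where masked out).
#' @param mask `n x T` logical matrix; defaults to `!is.na(labels)`.
#' @param tasks Optional task names (default: label column names).
#' @return A tibble of class `metrics_report`: one row per task plus one
#'   `"average"` row; columns `task`, `n`, `tp`, `tn`, `fp`, `fn`, `auc`,
#'   `f1`, `ba`, `mcc`, `se`, `sp`.
#' @export
evaluate_multitask <- function(preds, labels, mask = !is.na(labels),
                               tasks = colnames(labels)) {
  preds <- as.matrix(preds); labels <- as.matrix(labels); mask <- as.matrix(mask)
  stopifnot(all(dim(preds) == dim(labels)), all(dim(preds) == dim(mask)))
  if (is.null(tasks)) tasks <- paste0("task_", seq_len(ncol(preds)))

  rows <- purrr::map_dfr(seq_len(ncol(preds)), function(t) {
    m <- mask[, t] & !is.na(labels[, t])
    if (!any(m)) {
      warning("task ", tasks[t], ": no labelled molecules; all metrics undefined",
              call. = FALSE)
      return(tibble::tibble(task = tasks[t], n = 0L, tp = NA_integer_,
                            tn = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                            auc = NA_real_, f1 = NA_real_, ba = NA_real_,
                            mcc = NA_real_, se = NA_real_, sp = NA_real_))
    }
    cc <- confusion(preds[, t], labels[, t], m)
    auc_t <- tryCatch(auc(preds[, t], labels[, t], m), error = function(e) {
      warning("task ", tasks[t], ": ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
    tibble::tibble(task = tasks[t], n = sum(m), tp = cc$tp, tn = cc$tn,
                   fp = cc$fp, fn = cc$fn, auc = auc_t, f1 = f1(cc),
                   ba = balanced_accuracy(cc), mcc = mcc(cc),
                   se = sensitivity(cc), sp = specificity(cc))
  })
  avg <- tibble::tibble(
    task = "average", n = sum(rows$n),
    tp = NA_integer_, tn = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    auc = mean(rows$auc, na.rm = TRUE), f1 = mean(rows$f1, na.rm = TRUE),
    ba = mean(rows$ba, na.rm = TRUE), mcc = mean(rows$mcc, na.rm = TRUE),
    se = mean(rows$se, na.rm = TRUE), sp = mean(rows$sp, na.rm = TRUE)
  )
  out <- dplyr::bind_rows(rows, avg)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Evaluate a fitted model on a molecule dataset
#'
#' @param fit A `fpgnn_fit` (or `fpgnn_model`).
#' @param data A molecule dataset tibble with labels.
#' @return A `metrics_report` tibble (see [evaluate_multitask()]).
#' @export
evaluate_model <- function(fit, data) {
  model <- if (inherits(fit, "fpgnn_fit")) fit$model else fit
  tasks <- dataset_tasks(data)
  probs <- predict_prob_matrix(model, data$smiles_canonical, tasks)
  evaluate_multitask(probs, label_matrix(data), mask_matrix(data), tasks)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report A `metrics_report` tibble.
#' @param path_csv,path_json Output paths (either may be NULL to skip).
#' @return The report, invisibly.
#' @export
write_metrics <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) readr::write_csv(report, path_csv)
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
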