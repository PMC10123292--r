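# Euclidean-distance applicability domain (AD).
#
# Training side: for each training compound, the mean Euclidean distance to
# its k nearest other training compounds; d_ave and theta are the mean and
# (population) standard deviation of those per-compound means, and the
# threshold is D_T = d_ave + Z * theta. Query side: a compound is outside
# the domain (OD) iff the distance to its single nearest training compound
# exceeds D_T. Distances are computed on the raw concatenated mixed
# fingerprint vectors, without rescaling.

pairwise_dist <- function(A, B) {
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Fit the applicability-domain threshold
#'
#' @param train_fps Numeric matrix of training fingerprint vectors (rows =
#'   compounds), or a molecule dataset tibble (fingerprinted internally).
#' @param k Number of nearest neighbours for the training-side averages
#'   (1 <= k < number of training compounds).
#' @param Z Significance multiplier (unitless).
#' @return An object of class `ad_model`: `train_fps`, `k`, `Z`, `knn_mean`
#'   (per-compound k-NN average distance), `d_ave`, `theta` (population SD),
#'   and the threshold `D_T = d_ave + Z * theta`.
#' @export
fit_ad <- function(train_fps, k = 3, Z = 0.2) {
  if (is.data.frame(train_fps)) {
    train_fps <- fingerprint_matrix(train_fps$smiles_canonical)
  }
  train_fps <- as.matrix(train_fps)
  n <- nrow(train_fps)
  if (k < 1 || k >= n) {
    abort_fpgnn(sprintf("k = %d must satisfy 1 <= k < n_train = %d", k, n),
                "fpgnn_parameter_error")
  }
  D <- pairwise_dist(train_fps, train_fps)
  knn_mean <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    # ties broken by training index: sort() is stable on the index order
    mean(sort(d, method = "radix")[seq_len(k)])
  }, numeric(1))
  d_ave <- mean(knn_mean)
  theta <- sqrt(mean((knn_mean - d_ave)^2))
  structure(
    list(train_fps = train_fps, k = as.integer(k), Z = Z,
         knn_mean = knn_mean, d_ave = d_ave, theta = theta,
         D_T = d_ave + Z * theta),
    class = "ad_model"
  )
}

#' @export
print.ad_model <- function(x, ...) {
  cat("<ad_model> n_train=", nrow(x$train_fps), " k=", x$k, " Z=", x$Z,
      "; d_ave=", signif(x$d_ave, 5), " theta=", signif(x$theta, 5),
      " D_T=", signif(x$D_T, 5), "\n", sep = "")
  invisible(x)
}

#' Classify compounds as inside/outside the applicability domain
#'
#' Each query's Euclidean distance to its single nearest training compound
#' is compared with the fitted threshold: OD iff distance > D_T.
#'
#' @param query_fps Numeric matrix of query fingerprint vectors, or a
#'   molecule dataset tibble.
#' @param ad An `ad_model` from [fit_ad()].
#' @return A tibble with columns `distance` (nearest-neighbour distance to
#'   the training set), `nn_index` (index of that training compound) and
#'   `flag` (`"ID"` or `"OD"`).
#' @export
classify_ad <- function(query_fps, ad) {
  stopifnot(inherits(ad, "ad_model"))
  if (is.data.frame(query_fps)) {
    query_fps <- fingerprint_matrix(query_fps$smiles_canonical)
  }
  query_fps <- as.matrix(query_fps)
  if (ncol(query_fps) != ncol(ad$train_fps)) {
    abort_fpgnn(sprintf(
      "query fingerprint length %d does not match training length %d",
      ncol(query_fps), ncol(ad$train_fps)), "fpgnn_shape_error")
  }
  D <- pairwise_dist(query_fps, ad$train_fps)
  nn <- apply(D, 1, which.min)   # first minimum = lowest training index
  dist <- D[cbind(seq_len(nrow(D)), nn)]
  tibble::tibble(
    distance = dist, nn_index = as.integer(nn),
    flag = ifelse(dist > ad$D_T, "OD", "ID")
  )
}

#' Applicability-domain parameter grid
#'
#' For every (k, Z) pair: fits the AD on the training fingerprints,
#' classifies the test set, and evaluates the fitted model separately on the
#' inside-domain and outside-domain subsets. At fixed k the OD count is
#' nonincreasing in Z, since the threshold grows with Z.
#'
#' @param split A `dataset_split`.
#' @param fit A `fpgnn_fit` or `fpgnn_model` trained on the split.
#' @param k_values,Z_values Grids of k and Z values; the defaults include
#'   the canonical operating point (k = 3, Z = 0.2).
#' @return A tibble of class `ad_grid`: one row per (k, Z) with `n_id`,
#'   `n_od` and averaged metrics (`auc_id`, `f1_id`, `ba_id`, `mcc_id`, and
#'   the `_od` counterparts; NA where a subset breaks a metric
#'   precondition).
#' @export
ad_grid <- function(split, fit, k_values = c(1, 3, 5), Z_values = c(0, 0.2, 0.5, 1)) {
  stopifnot(inherits(split, "dataset_split"))
  if (length(k_values) == 0 || length(Z_values) == 0) {
    abort_fpgnn("k_values and Z_values must be nonempty", "fpgnn_parameter_error")
  }
  model <- if (inherits(fit, "fpgnn_fit")) fit$model else fit
  tasks <- dataset_tasks(split$test)
  train_fps <- fingerprint_matrix(split$train$smiles_canonical)
  test_fps <- fingerprint_matrix(split$test$smiles_canonical)
  probs <- predict_prob_matrix(model, split$test$smiles_canonical, tasks)
  labels <- label_matrix(split$test)
  mask <- mask_matrix(split$test)

  avg_metrics <- function(idx, suffix) {
    if (length(idx) == 0) {
      out <- tibble::tibble(auc = NA_real_, f1 = NA_real_, ba = NA_real_, mcc = NA_real_)
    } else {
      rep_t <- suppressWarnings(evaluate_multitask(
        probs[idx, , drop = FALSE], labels[idx, , drop = FALSE],
        mask[idx, , drop = FALSE], tasks))
      avg <- rep_t[rep_t$task == "average", ]
      out <- tibble::tibble(auc = avg$auc, f1 = avg$f1, ba = avg$ba, mcc = avg$mcc)
    }
    stats::setNames(out, paste0(names(out), "_", suffix))
  }

  out <- purrr::map_dfr(k_values, function(k) {
    purrr::map_dfr(Z_values, function(z) {
      ad <- fit_ad(train_fps, k = k, Z = z)
      cls <- classify_ad(test_fps, ad)
      id_idx <- which(cls$flag == "ID"); od_idx <- which(cls$flag == "OD")
      dplyr::bind_cols(
        tibble::tibble(k = k, Z = z, D_T = ad$D_T,
                       n_id = length(id_idx), n_od = length(od_idx)),
        avg_metrics(id_idx, "id"),
        avg_metrics(od_idx, "od")
      )
    })
  })
  class(out) <- c("ad_grid", class(out))
  out
}
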