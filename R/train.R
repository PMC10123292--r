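# Training: Adam optimization of the masked multi-task BCE loss, validation
# AUC model selection with early stopping, hyperparameter search, and
# Y-scrambling validation.

#' Training configuration
#'
#' @param epochs Maximum number of epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without validation improvement (0 = stop at the first
#'   epoch that does not improve).
#' @param seed Integer seed controlling shuffling, dropout and scrambling.
#' @param scramble_rounds Default number of Y-scrambling rounds.
#' @return An object of class `train_config`. Model selection uses the
#'   averaged validation AUC.
#' @export
train_config <- function(epochs = 30, batch_size = 64, lr = 5e-3,
                         patience = 10, seed = 1, scramble_rounds = 5) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, patience >= 0)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, patience = as.integer(patience), seed = as.integer(seed),
         scramble_rounds = as.integer(scramble_rounds),
         selection_metric = "auc"),
    class = "train_config"
  )
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# Featurize every molecule of a dataset; molecules that fail featurization
# are dropped with a message. Returns fingerprints, graphs and labels.
prepare_training_data <- function(data) {
  ok <- rep(TRUE, nrow(data))
  graphs <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    g <- tryCatch(mol_to_graph(data$smiles_canonical[i]), error = function(e) NULL)
    if (is.null(g)) ok[i] <- FALSE else graphs[[i]] <- g
  }
  if (any(!ok)) {
    message(sum(!ok), " molecule(s) dropped: featurization failed")
  }
  data <- data[ok, , drop = FALSE]
  graphs <- graphs[ok]
  list(
    data = data,
    FP = fingerprint_matrix(data$smiles_canonical),
    graphs = graphs,
    labels = label_matrix(data),
    mask = mask_matrix(data)
  )
}

val_auc_by_task <- function(probs, labels, mask) {
  vapply(seq_len(ncol(labels)), function(t) {
    m <- mask[, t]
    y <- labels[m, t]
    if (length(unique(y)) < 2) return(NA_real_)
    auc(probs[m, t], y, rep(TRUE, sum(m)))
  }, numeric(1))
}

#' Train an FP-GNN model
#'
#' Gradient-based (Adam) optimization of the masked multi-task binary
#' cross-entropy loss on the training set of a [cluster_split()]. After each
#' epoch the averaged validation AUC is computed; the best-epoch parameters
#' are kept and training stops early after `patience` epochs without
#' improvement.
#'
#' @param split A `dataset_split` (only `train` and `validation` are used).
#' @param mcfg A [model_config()]; its `n_tasks` must match the dataset.
#' @param tcfg A [train_config()].
#' @return An object of class `fpgnn_fit`: a list with `model` (the
#'   best-epoch `fpgnn_model`), `history` (per-epoch tibble of training loss
#'   and per-task/averaged validation AUC) and `best_epoch`.
#' @export
train_model <- function(split, mcfg, tcfg = train_config()) {
  stopifnot(inherits(split, "dataset_split"), inherits(mcfg, "model_config"))
  tasks <- dataset_tasks(split$train)
  if (length(tasks) != mcfg$n_tasks) {
    abort_fpgnn(sprintf("model has T=%d tasks but the dataset has %d",
                        mcfg$n_tasks, length(tasks)), "fpgnn_shape_error")
  }
  tr <- prepare_training_data(split$train)
  va <- prepare_training_data(split$validation)
  if (nrow(tr$data) == 0) {
    abort_fpgnn("empty training set after featurization", "fpgnn_empty_dataset_error")
  }
  train_model_impl(tr, va, mcfg, tcfg, tasks)
}

train_model_impl <- function(tr, va, mcfg, tcfg, tasks) {
  model <- init_model(mcfg)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  va_batch <- batch_graphs(va$graphs)
  n <- nrow(tr$data)

  history <- list()
  best <- list(auc = -Inf, epoch = 0L, theta = theta)
  since_best <- 0L

  with_seed(derive_seed(tcfg$seed, "train"), {
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
      epoch_loss <- 0; n_seen <- 0
      for (b in batches) {
        # skip batches with no labelled entry at all
        if (!any(tr$mask[b, , drop = FALSE])) next
        batch <- batch_graphs(tr$graphs[b])
        fwd <- forward_batch(model, tr$FP[b, , drop = FALSE], batch, training = TRUE)
        lg <- loss_and_grad(fwd$logits, tr$labels[b, , drop = FALSE],
                            tr$mask[b, , drop = FALSE])
        if (!is.finite(lg$loss)) {
          abort_fpgnn(sprintf(
            "training diverged (non-finite loss) at epoch %d; lower the learning rate",
            epoch), "fpgnn_divergence_error")
        }
        grads <- backward_batch(model, tr$FP[b, , drop = FALSE], batch, fwd, lg$dlogits)
        st <- adam_step(opt, theta, flatten_params(grads), tcfg$lr)
        opt <- st$state; theta <- st$theta
        model$params <- unflatten_params(model$params, theta)
        epoch_loss <- epoch_loss + lg$loss * length(b)
        n_seen <- n_seen + length(b)
      }
      fwd_va <- forward_batch(model, va$FP, va_batch, training = FALSE)
      aucs <- val_auc_by_task(fwd_va$probs, va$labels, va$mask)
      avg_auc <- mean(aucs, na.rm = TRUE)
      row <- c(list(epoch = epoch, train_loss = epoch_loss / n_seen),
               stats::setNames(as.list(aucs), paste0("val_auc_", tasks)),
               list(val_auc_avg = avg_auc))
      history[[epoch]] <- tibble::as_tibble(row)
      if (is.finite(avg_auc) && avg_auc > best$auc) {
        best <- list(auc = avg_auc, epoch = epoch, theta = theta)
        since_best <- 0L
      } else {
        # ties keep the later epoch (same AUC, lower loss) but still count
        # towards the early-stopping patience
        if (is.finite(avg_auc) && avg_auc == best$auc) {
          best <- list(auc = avg_auc, epoch = epoch, theta = theta)
        }
        since_best <- since_best + 1L
        if (since_best > tcfg$patience) break
      }
    }
  })

  final_model <- model
  final_model$params <- unflatten_params(model$params, theta)
  model$params <- unflatten_params(model$params, best$theta)
  model$meta$epoch <- best$epoch
  model$meta$best_val_auc <- best$auc
  model$meta$tasks <- tasks
  final_model$meta <- model$meta
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, final_model = final_model),
    class = "fpgnn_fit"
  )
}

#' @export
print.fpgnn_fit <- function(x, ...) {
  cat("<fpgnn_fit> best epoch ", x$best_epoch, ", validation AUC ",
      signif(x$model$meta$best_val_auc, 4), " (", nrow(x$history),
      " epochs trained)\n", sep = "")
  invisible(x)
}

#' @method tidy fpgnn_fit
#' @export
tidy.fpgnn_fit <- function(x, ...) x$history

#' @method glance fpgnn_fit
#' @export
glance.fpgnn_fit <- function(x, ...) {
  tibble::tibble(
    best_epoch = x$best_epoch,
    epochs_trained = nrow(x$history),
    best_val_auc = x$model$meta$best_val_auc,
    final_train_loss = utils::tail(x$history$train_loss, 1)
  )
}

#' Hyperparameter search by validation AUC
#'
#' Trains `budget` configurations drawn (seeded, without replacement when
#' possible) from a named grid of [model_config()] arguments, ranks them by
#' averaged validation AUC and returns the winner with the full leaderboard.
#'
#' @param split A `dataset_split`.
#' @param space Named list of candidate values, e.g.
#'   `list(gnn_hidden = c(16, 32), dropout = c(0, 0.1))`.
#' @param budget Number of configurations to train (>= 1).
#' @param tcfg A [train_config()].
#' @param seed Integer seed for drawing configurations.
#' @return A list of class `fpgnn_search`: `best_config`, `best_fit`, and
#'   `leaderboard` (tibble sorted by decreasing validation AUC).
#' @export
hyperparameter_search <- function(split, space, budget, tcfg = train_config(),
                                  seed = 1) {
  if (length(space) == 0) {
    abort_fpgnn("empty hyperparameter space", "fpgnn_parameter_error")
  }
  if (budget < 1) {
    abort_fpgnn("budget must be >= 1", "fpgnn_parameter_error")
  }
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  picks <- with_seed(derive_seed(seed, "hpo"), {
    sample.int(nrow(grid), min(budget, nrow(grid)))
  })
  tasks <- dataset_tasks(split$train)
  rows <- list(); fits <- list()
  for (i in seq_along(picks)) {
    args <- as.list(grid[picks[i], , drop = FALSE])
    args$n_tasks <- length(tasks)
    args$seed <- derive_seed(seed, "hpo-model", i)
    mcfg <- do.call(model_config, args)
    fit <- train_model(split, mcfg, tcfg)
    fits[[i]] <- fit
    rows[[i]] <- dplyr::bind_cols(
      tibble::as_tibble(grid[picks[i], , drop = FALSE]),
      tibble::tibble(candidate = i, val_auc = fit$model$meta$best_val_auc,
                     best_epoch = fit$best_epoch)
    )
  }
  leaderboard <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$val_auc))
  winner <- leaderboard$candidate[1]
  structure(
    list(best_config = fits[[winner]]$model$config, best_fit = fits[[winner]],
         leaderboard = leaderboard),
    class = "fpgnn_search"
  )
}

#' Y-scrambling validation
#'
#' Retrains the model `rounds` times with the response permuted within each
#' task across the modeling data — training and validation labels alike,
#' masks untouched so class balance per task is preserved — and records
#' test-set AUCs, together with the unscrambled reference fit. Each
#' scrambled round records the completed retrain (final epoch): under a
#' permuted response, validation-based epoch selection is pure noise and
#' would favour barely-trained snapshots that retain accidental
#' initialization correlations. A real structure-activity relationship
#' collapses to AUC near 0.5 under scrambling.
#'
#' @param split A `dataset_split` (train/validation/test).
#' @param mcfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param rounds Number of scrambled retrains (>= 1).
#' @return A tibble of class `y_scramble_result`: columns `round` (0 is the
#'   unscrambled reference), `scrambled`, one AUC column per task, and
#'   `auc_avg`. Failed rounds are recorded with NA AUCs.
#' @export
y_scramble <- function(split, mcfg, tcfg = train_config(),
                       rounds = tcfg$scramble_rounds) {
  if (rounds < 1) {
    abort_fpgnn("rounds must be >= 1", "fpgnn_parameter_error")
  }
  tasks <- dataset_tasks(split$train)
  te <- prepare_training_data(split$test)
  te_batch <- batch_graphs(te$graphs)

  eval_test <- function(fit, use_final = FALSE) {
    m <- if (use_final) fit$final_model else fit$model
    fwd <- forward_batch(m, te$FP, te_batch, training = FALSE)
    val_auc_by_task(fwd$probs, te$labels, te$mask)
  }

  ref_fit <- train_model(split, mcfg, tcfg)
  ref_auc <- eval_test(ref_fit)

  rows <- list()
  rows[[1]] <- tibble::as_tibble(c(
    list(round = 0L, scrambled = FALSE),
    stats::setNames(as.list(ref_auc), paste0("auc_", tasks)),
    list(auc_avg = mean(ref_auc, na.rm = TRUE))
  ))

  for (r in seq_len(rounds)) {
    scr <- split
    scr$train <- scramble_labels(split$train, derive_seed(tcfg$seed, "scramble", r))
    scr$validation <- scramble_labels(split$validation,
                                      derive_seed(tcfg$seed, "scramble-val", r))
    mcfg_r <- mcfg
    mcfg_r$seed <- derive_seed(mcfg$seed, "scramble-init", r)
    tcfg_r <- tcfg
    tcfg_r$seed <- derive_seed(tcfg$seed, "scramble-train", r)
    aucs <- tryCatch(eval_test(train_model(scr, mcfg_r, tcfg_r),
                               use_final = TRUE),
                     error = function(e) {
                       warning("scramble round ", r, " failed: ",
                               conditionMessage(e), call. = FALSE)
                       rep(NA_real_, length(tasks))
                     })
    rows[[r + 1]] <- tibble::as_tibble(c(
      list(round = r, scrambled = TRUE),
      stats::setNames(as.list(aucs), paste0("auc_", tasks)),
      list(auc_avg = mean(aucs, na.rm = TRUE))
    ))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("y_scramble_result", class(out))
  attr(out, "tasks") <- tasks
  out
}

# permute present labels within each task (per-task permutation keeps class
# balance; masks are left in place)
scramble_labels <- function(data, seed) {
  tasks <- dataset_tasks(data)
  with_seed(seed, {
    for (t in tasks) {
      present <- which(!is.na(data[[t]]))
      data[[t]][present] <- data[[t]][present][sample.int(length(present))]
    }
  })
  data
}
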