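# Dataset curation: reading, cleaning, canonicalization, deduplication,
# structure-based cluster splitting, and chemical-space profiling.
#
# A molecule dataset is an ordinary tibble with columns `id`, `smiles`,
# `smiles_canonical`, and one 0/1/NA column per task (NA = label missing,
# i.e. masked out). The task column names are carried in the
# `fpgnn_tasks` attribute.

new_mol_dataset <- function(df, tasks) {
  stopifnot(all(c("id", "smiles", "smiles_canonical") %in% names(df)),
            all(tasks %in% names(df)))
  attr(df, "fpgnn_tasks") <- tasks
  df
}

#' Task names of a molecule dataset
#' @param data A molecule dataset tibble (see [read_dataset()]).
#' @return Character vector of task (label column) names.
#' @export
dataset_tasks <- function(data) {
  tasks <- attr(data, "fpgnn_tasks")
  if (is.null(tasks)) {
    tasks <- setdiff(names(data), c("id", "smiles", "smiles_canonical"))
  }
  tasks
}

#' Label and mask matrices of a dataset
#'
#' @param data A molecule dataset tibble.
#' @return `label_matrix()`: numeric `n x T` matrix with NA where the label
#'   is missing. `mask_matrix()`: logical `n x T`, TRUE where a label is
#'   present.
#' @export
label_matrix <- function(data) {
  tasks <- dataset_tasks(data)
  m <- as.matrix(as.data.frame(data[, tasks, drop = FALSE]))
  storage.mode(m) <- "double"
  dimnames(m) <- list(data$id, tasks)
  m
}

#' @rdname label_matrix
#' @export
mask_matrix <- function(data) !is.na(label_matrix(data))

#' Read a molecule dataset from CSV
#'
#' The file must contain a SMILES column (named `smiles`, case-insensitive)
#' and one 0/1 column per task; empty cells mean the label is missing for
#' that molecule/task. Rows whose SMILES does not parse are dropped with a
#' warning reporting the count.
#'
#' @param path Path to a CSV file.
#' @param task_names Character vector of task column names. Default: every
#'   column other than `id`/`smiles`.
#' @return A molecule dataset tibble (columns `id`, `smiles`,
#'   `smiles_canonical`, one column per task).
#' @export
read_dataset <- function(path, task_names = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  smi_col <- names(df)[tolower(names(df)) == "smiles"]
  if (length(smi_col) == 0) {
    abort_fpgnn("input CSV has no SMILES column", "fpgnn_config_error")
  }
  smi_col <- smi_col[1]
  if (is.null(task_names)) {
    task_names <- setdiff(names(df), c(smi_col, "id"))
  }
  missing_tasks <- setdiff(task_names, names(df))
  if (length(missing_tasks) > 0) {
    abort_fpgnn(paste0("task column(s) not in CSV: ",
                       paste(missing_tasks, collapse = ", ")),
                "fpgnn_config_error")
  }
  ids <- if ("id" %in% names(df)) as.character(df$id) else sprintf("mol_%04d", seq_len(nrow(df)))

  out <- tibble::tibble(
    id = ids,
    smiles = as.character(df[[smi_col]]),
    smiles_canonical = canonical_smiles(df[[smi_col]])
  )
  for (t in task_names) out[[t]] <- as.numeric(df[[t]])

  bad <- is.na(out$smiles_canonical)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparsable SMILES dropped: ",
            paste(utils::head(out$smiles[bad], 5), collapse = ", "),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    abort_fpgnn("no parsable molecules in input", "fpgnn_empty_dataset_error")
  }
  new_mol_dataset(out, task_names)
}

#' Write a molecule dataset to CSV
#'
#' Emits the same CSV dialect that [read_dataset()] reads (labels as 0/1,
#' missing labels as empty cells).
#'
#' @param data A molecule dataset tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  out <- data[, c("id", "smiles", dataset_tasks(data))]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Clean a molecule dataset
#'
#' Applies, in order: (1) removal of molecules without a carbon atom
#' (inorganics); (2) for multi-fragment SMILES, retention of the largest
#' carbon-containing fragment by heavy-atom count (salt/mixture handling);
#' (3) canonicalization; (4) deduplication by canonical SMILES with label
#' merging — duplicates that disagree on a task label have that label set to
#' missing. Removal counts at each step are attached as the
#' `cleaning_counts` attribute.
#'
#' @param data A molecule dataset tibble.
#' @return The cleaned dataset tibble; `attr(, "cleaning_counts")` holds the
#'   per-step removal counts.
#' @export
clean_dataset <- function(data) {
  tasks <- dataset_tasks(data)
  n0 <- nrow(data)

  # (1)+(2): fragment handling on the canonical form
  keep_smiles <- character(nrow(data))
  inorganic <- logical(nrow(data))
  for (r in seq_len(nrow(data))) {
    frags <- strsplit(data$smiles_canonical[r], ".", fixed = TRUE)[[1]]
    best <- NA_character_; best_n <- -1L
    for (f in frags) {
      fi <- parse_smiles(f)
      if (!isTRUE(fi$valid)) next
      if (!any(fi$atoms$element == "C")) next
      if (nrow(fi$atoms) > best_n) {
        best_n <- nrow(fi$atoms)
        best <- fi$smiles_canonical
      }
    }
    if (is.na(best)) inorganic[r] <- TRUE else keep_smiles[r] <- best
  }
  out <- data[!inorganic, , drop = FALSE]
  out$smiles_canonical <- keep_smiles[!inorganic]
  n_inorganic <- sum(inorganic)

  # (4): deduplicate by canonical SMILES, merging label vectors
  merged <- out |>
    dplyr::group_by(.data$smiles_canonical) |>
    dplyr::summarise(
      id = dplyr::first(.data$id),
      smiles = dplyr::first(.data$smiles),
      dplyr::across(dplyr::all_of(tasks), merge_labels),
      .groups = "drop"
    )
  # preserve first-appearance order
  merged <- merged[order(match(merged$smiles_canonical, out$smiles_canonical)), ]
  merged <- merged[, c("id", "smiles", "smiles_canonical", tasks)]
  n_dupe <- nrow(out) - nrow(merged)

  counts <- c(input = n0, inorganic_removed = n_inorganic,
              duplicates_merged = n_dupe, output = nrow(merged))
  res <- new_mol_dataset(tibble::as_tibble(merged), tasks)
  attr(res, "cleaning_counts") <- counts
  res
}

merge_labels <- function(x) {
  vals <- unique(x[!is.na(x)])
  if (length(vals) == 1) vals else NA_real_
}

#' Structure-based cluster split
#'
#' Clusters molecules by k-means on their mixed fingerprint vectors and draws
#' validation and test sets proportionally from each cluster (stratified,
#' seeded), leaving the remainder as training data.
#'
#' @param data A molecule dataset tibble.
#' @param k Number of k-means clusters (>= 1).
#' @param n_valid,n_test Validation/test set sizes; their sum must be smaller
#'   than the number of molecules.
#' @param seed Integer seed controlling clustering restarts and sampling.
#' @return An object of class `dataset_split`: a list with elements `train`,
#'   `validation`, `test` (molecule dataset tibbles) and `meta` (k, seed,
#'   within-cluster sum of squares, cluster sizes, cluster assignments).
#' @export
cluster_split <- function(data, k = 6, n_valid, n_test, seed = 1) {
  n <- nrow(data)
  if (k < 1 || k > n) {
    abort_fpgnn(sprintf("k = %d must be in 1..%d (number of records)", k, n),
                "fpgnn_parameter_error")
  }
  if (n_valid + n_test >= n) {
    abort_fpgnn("n_valid + n_test must be smaller than the number of records",
                "fpgnn_parameter_error")
  }
  X <- fingerprint_matrix(data$smiles_canonical)
  km <- fit_kmeans(X, k, seed)
  cl <- km$cluster

  sizes <- tabulate(cl, nbins = k)
  quota_v <- proportional_quota(sizes, n_valid)
  quota_t <- proportional_quota(sizes, n_test)

  idx_valid <- integer(0); idx_test <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (c_i in seq_len(k)) {
      members <- which(cl == c_i)
      take <- min(quota_v[c_i] + quota_t[c_i], length(members))
      picked <- if (length(members) == 1 && take == 1) members else
        sample(members, take)
      idx_valid <- c(idx_valid, picked[seq_len(min(quota_v[c_i], length(picked)))])
      if (take > quota_v[c_i]) {
        idx_test <- c(idx_test, picked[(quota_v[c_i] + 1):take])
      }
    }
  })
  idx_valid <- sort(idx_valid); idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(n), c(idx_valid, idx_test))

  tasks <- dataset_tasks(data)
  structure(
    list(
      train = new_mol_dataset(data[idx_train, , drop = FALSE], tasks),
      validation = new_mol_dataset(data[idx_valid, , drop = FALSE], tasks),
      test = new_mol_dataset(data[idx_test, , drop = FALSE], tasks),
      meta = list(k = k, seed = seed, wss = km$tot.withinss,
                  cluster_sizes = sizes, cluster = cl)
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train ", nrow(x$train), " / validation ",
      nrow(x$validation), " / test ", nrow(x$test),
      "; k = ", x$meta$k, ", WSS = ", signif(x$meta$wss, 6), "\n", sep = "")
  invisible(x)
}

# largest-remainder proportional allocation, deterministic tie-break by index
proportional_quota <- function(sizes, total) {
  if (total == 0) return(integer(length(sizes)))
  raw <- total * sizes / sum(sizes)
  q <- floor(raw)
  rem <- total - sum(q)
  if (rem > 0) {
    ord <- order(raw - q, sizes, decreasing = TRUE)
    q[ord[seq_len(rem)]] <- q[ord[seq_len(rem)]] + 1
  }
  # never allocate more than a cluster holds
  over <- q > sizes
  while (any(over)) {
    excess <- sum(q[over] - sizes[over])
    q[over] <- sizes[over]
    room <- which(q < sizes)
    room <- room[order(sizes[room] - q[room], decreasing = TRUE)]
    for (i in room) {
      if (excess == 0) break
      add <- min(excess, sizes[i] - q[i])
      q[i] <- q[i] + add
      excess <- excess - add
    }
    over <- q > sizes
    if (excess > 0 && length(room) == 0) break
  }
  as.integer(q)
}

fit_kmeans <- function(X, k, seed) {
  n_unique <- nrow(unique(X))
  if (k >= n_unique) {
    # degenerate: every distinct point is its own center, WSS exactly 0
    keyify <- apply(X, 1, paste, collapse = ",")
    cl <- as.integer(factor(keyify, levels = unique(keyify)))
    return(list(cluster = cl, tot.withinss = 0))
  }
  with_seed(derive_seed(seed, "kmeans", k), {
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 50)
  })
}

#' Within-cluster sum of squares across k (elbow curve)
#'
#' Runs seeded k-means with multiple restarts for k = 1..`k_max` on the mixed
#' fingerprint vectors and reports the within-cluster sum of squares, for
#' choosing the split granularity by the elbow criterion.
#'
#' @param data A molecule dataset tibble.
#' @param k_max Largest k to evaluate (>= 2).
#' @param seed Integer seed.
#' @return A tibble with columns `k` and `wss`, of class `elbow_curve`.
#' @export
elbow_curve <- function(data, k_max, seed = 1) {
  if (k_max < 2) {
    abort_fpgnn("k_max must be >= 2", "fpgnn_parameter_error")
  }
  X <- fingerprint_matrix(data$smiles_canonical)
  out <- purrr::map_dfr(seq_len(k_max), function(k) {
    wss <- if (k == 1) {
      sum(scale(X, scale = FALSE)^2)
    } else {
      fit_kmeans(X, k, seed)$tot.withinss
    }
    tibble::tibble(k = k, wss = wss)
  })
  class(out) <- c("elbow_curve", class(out))
  out
}

# ---------------------------------------------------------------------------
# Profiling

# Bemis-Murcko-style scaffold: iteratively prune terminal (degree-1) atoms;
# what remains is the ring systems plus linkers. Acyclic molecules map to the
# empty scaffold "" (fixed convention so the scaffold fraction is defined).
murcko_scaffold <- function(smiles) {
  info <- parse_smiles(smiles)
  if (!isTRUE(info$valid)) return(NA_character_)
  if (!any(info$atoms$in_ring)) return("")
  keep <- rep(TRUE, nrow(info$atoms))
  b <- info$bonds
  repeat {
    deg <- tabulate(c(b$i[keep[b$i] & keep[b$j]], b$j[keep[b$i] & keep[b$j]]),
                    nbins = nrow(info$atoms))
    prune <- keep & deg <= 1 & !info$atoms$in_ring
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  fragment_canonical(info, which(keep))
}

#' Profile a molecule dataset
#'
#' Computes molecular weight and LogP per molecule, Bemis-Murcko scaffolds,
#' the scaffold fraction (unique scaffolds / molecules), and per-task label
#' counts.
#'
#' @param data A molecule dataset tibble.
#' @return An object of class `dataset_profile`: a list with `molecules` (a
#'   tibble of id, mw, logp, scaffold), `scaffold_fraction`, `task_counts`
#'   (tibble of positives/negatives/missing per task), and the MW/LogP
#'   ranges.
#' @export
profile_dataset <- function(data) {
  props <- purrr::map_dfr(data$smiles_canonical, function(s) {
    key <- paste0("prop:", s)
    hit <- cache_get("prop", key)
    if (is.null(hit)) {
      p <- ChemmineOB::prop_OB(list(ob_mol(s)))
      hit <- tibble::tibble(mw = p$MW, logp = p$logP)
      cache_set("prop", key, hit)
    }
    hit
  })
  scaffolds <- vapply(data$smiles_canonical, murcko_scaffold, character(1),
                      USE.NAMES = FALSE)
  labels <- label_matrix(data)
  task_counts <- tibble::tibble(
    task = dataset_tasks(data),
    positives = unname(colSums(labels == 1, na.rm = TRUE)),
    negatives = unname(colSums(labels == 0, na.rm = TRUE)),
    missing = unname(colSums(is.na(labels)))
  )
  structure(
    list(
      molecules = tibble::tibble(id = data$id, mw = props$mw, logp = props$logp,
                                 scaffold = scaffolds),
      scaffold_fraction = length(unique(scaffolds)) / nrow(data),
      mw_range = range(props$mw),
      logp_range = range(props$logp),
      task_counts = task_counts
    ),
    class = "dataset_profile"
  )
}

#' @export
print.dataset_profile <- function(x, ...) {
  cat("<dataset_profile> ", nrow(x$molecules), " molecules\n",
      "  MW ", signif(x$mw_range[1], 6), "-", signif(x$mw_range[2], 6),
      " Da; LogP ", signif(x$logp_range[1], 4), "-", signif(x$logp_range[2], 4), "\n",
      "  scaffold fraction ", signif(x$scaffold_fraction, 4), "\n", sep = "")
  print(x$task_counts)
  invisible(x)
}

#' Write a dataset split to disk
#'
#' Writes train/validation/test CSVs plus a JSON sidecar with the seed, k,
#' within-cluster sum of squares and cluster sizes.
#'
#' @param split A `dataset_split` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(split$train, file.path(dir, "train.csv"))
  write_dataset(split$validation, file.path(dir, "validation.csv"))
  write_dataset(split$test, file.path(dir, "test.csv"))
  meta <- split$meta
  meta$cluster <- NULL
  jsonlite::write_json(meta, file.path(dir, "split.json"), auto_unbox = TRUE)
  invisible(dir)
}
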