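# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_fpgnn <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fpgnn_error"))
}

# Deterministic child seeds: expand one top-level seed into per-component
# streams without ever exceeding .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) {
      h <- (h * 31 + ch) %% 2147483563
    }
  }
  as.integer(h) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Polynomial string hash, used to version feature schemas in checkpoints.
schema_hash <- function(x) {
  s <- paste(x, collapse = "|")
  h <- 17
  for (ch in utf8ToInt(s)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Sum rows of `x` within groups given by sorted integer `g` (1..n_groups).
segment_sum <- function(x, g, n_groups) {
  if (is.matrix(x)) {
    out <- rowsum(x, g, reorder = TRUE)
    full <- matrix(0, n_groups, ncol(x))
    full[as.integer(rownames(out)), ] <- out
    full
  } else {
    out <- rowsum(matrix(x, ncol = 1), g, reorder = TRUE)
    full <- numeric(n_groups)
    full[as.integer(rownames(out))] <- out[, 1]
    full
  }
}

# Softmax of `u` within groups `g` (integers 1..n_groups, every group
# nonempty); `idx` is the list of per-group index vectors, precomputed once
# per batch with split(). Returns the normalized weights.
segment_softmax <- function(u, g, idx, n_groups) {
  gmax <- vapply(idx, function(ii) max(u[ii]), numeric(1))
  e <- exp(u - gmax[g])
  denom <- segment_sum(e, g, n_groups)
  e / denom[g]
}

relu <- function(x) (x > 0) * x
lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
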