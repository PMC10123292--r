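# Synthetic multi-task molecular datasets with known structure-label rules.
#
# Molecules are assembled from a scaffold x substituent grammar (aromatic and
# aliphatic rings, chains, halogen / nitro / carboxyl / sulfonamide / nitrile
# fragments). Each task's label is a deterministic SMARTS match on the
# assembled molecule, optionally XOR-ed with seeded noise and masked at a
# per-task missing-label rate. A correlation knob attaches one shared latent
# substructure that all task rules also match, emulating related tasks that
# reward multi-task learning.

.synth_tasks_default <- list(
  nitro = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
  sulfonamide = "[SX4](=[OX1])(=[OX1])[NX3]",
  carboxyl = "[CX3](=[OX1])[OX2H1]",
  halogen = "[Cl,Br,I]",
  nitrile = "[CX2]#[NX1]"
)

.synth_fragments <- list(
  nitro = "[N+](=O)[O-]",
  sulfonamide = "S(N)(=O)=O",
  carboxyl = "C(=O)O",
  halogen = c("Cl", "Br"),
  nitrile = "C#N"
)

.synth_shared_fragment <- "C(F)(F)F"
.synth_shared_smarts <- "[CX4]([F])([F])[F]"

.synth_decoys <- c("C", "CC", "C(C)C", "O", "OC", "OCC", "C=C", "CCO")

# templates are sprintf patterns; each %s is a substitution slot
.synth_templates <- list(
  list(pattern = "c1c%sc%sc%sc%sc1%s", slots = 5L),
  list(pattern = "c1%sc%sc%sc%sc%sn1", slots = 5L),
  list(pattern = "C1C%sC%sC%sC%sC1%s", slots = 5L),
  list(pattern = "C1C%sC%sC%sC%sN1", slots = 4L),
  list(pattern = "c1c%sc%sc%ss1", slots = 3L),
  list(pattern = "c1c%sc%sc%so1", slots = 3L),
  list(pattern = "CC%sC%sC%sC%sC%s", slots = 5L)
)

#' Specification for a synthetic dataset
#'
#' @param n Number of (unique) molecules to generate.
#' @param tasks Named list of task-defining SMARTS patterns. Defaults to five
#'   tasks keyed on nitro, sulfonamide, carboxyl, halogen and nitrile
#'   substructures.
#' @param noise Per-label flip probability in `[0, 0.5)`.
#' @param missing Per-task missing-label probability in `[0, 1)`.
#' @param balance Target positive fraction per task.
#' @param correlation Probability of attaching a shared latent substructure
#'   (trifluoromethyl) that every task's rule also matches; 0 disables it.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n = 500, tasks = .synth_tasks_default, noise = 0,
                       missing = 0, balance = 0.5, correlation = 0, seed = 1) {
  stopifnot(n >= 1, length(tasks) >= 1, !is.null(names(tasks)),
            noise >= 0, noise < 0.5, missing >= 0, missing < 1,
            balance > 0, balance < 1, correlation >= 0, correlation <= 1)
  structure(
    list(n = as.integer(n), tasks = tasks, noise = noise, missing = missing,
         balance = balance, correlation = correlation, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> n=", x$n, " T=", length(x$tasks),
      " noise=", x$noise, " missing=", x$missing,
      " balance=", x$balance, " correlation=", x$correlation,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

branchify <- function(x) ifelse(nzchar(x), paste0("(", x, ")"), "")

assemble_molecule <- function(spec, task_names) {
  tpl <- .synth_templates[[sample.int(length(.synth_templates), 1)]]
  want <- task_names[stats::runif(length(task_names)) < spec$balance]
  frags <- vapply(want, function(t) {
    pool <- .synth_fragments[[t]] %||% "C"
    pool[sample.int(length(pool), 1)]
  }, character(1))
  if (spec$correlation > 0 && stats::runif(1) < spec$correlation) {
    frags <- c(frags, .synth_shared_fragment)
  }
  if (length(frags) > tpl$slots) {
    frags <- frags[sample.int(length(frags), tpl$slots)]
  }
  subs <- character(tpl$slots)
  if (length(frags) > 0) {
    pos <- sample.int(tpl$slots, length(frags))
    subs[pos] <- frags
  }
  empty <- which(!nzchar(subs))
  for (e in empty) {
    if (stats::runif(1) < 0.4) {
      subs[e] <- .synth_decoys[sample.int(length(.synth_decoys), 1)]
    }
  }
  # the last slot of 5-slot templates is appended bare (no branch parens)
  bare_last <- grepl("1%s$", tpl$pattern) || grepl("C%s$", tpl$pattern)
  args <- as.list(branchify(subs))
  if (bare_last) args[[tpl$slots]] <- subs[tpl$slots]
  do.call(sprintf, c(list(tpl$pattern), args))
}

task_rule_match <- function(smiles, smarts, spec) {
  m <- smarts_count(smiles, smarts)
  hit <- !is.na(m) && m >= 1
  if (!hit && spec$correlation > 0) {
    s <- smarts_count(smiles, .synth_shared_smarts)
    hit <- !is.na(s) && s >= 1
  }
  hit
}

#' Generate a synthetic molecule dataset
#'
#' Assembles `n` unique molecules from the scaffold/substituent grammar and
#' labels each task by its SMARTS rule (with the shared substructure OR-ed in
#' when `correlation > 0`), flips labels with probability `noise`, and masks
#' labels with probability `missing`. Deterministic given the spec.
#'
#' @param spec A [synth_spec()].
#' @return A molecule dataset tibble (as from [read_dataset()]), with the
#'   spec attached as the `synth_spec` attribute.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  task_names <- names(spec$tasks)
  with_seed(derive_seed(spec$seed, "synth"), {
    seen <- character(0)
    smiles <- character(0)
    tries <- 0
    while (length(smiles) < spec$n && tries < 30 * spec$n) {
      tries <- tries + 1
      s <- assemble_molecule(spec, task_names)
      can <- canonical_smiles(s)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      smiles <- c(smiles, s)
    }
    if (length(smiles) < spec$n) {
      warning("grammar exhausted: generated ", length(smiles),
              " unique molecules of ", spec$n, " requested", call. = FALSE)
    }
    out <- tibble::tibble(
      id = sprintf("syn_%05d", seq_along(smiles)),
      smiles = smiles,
      smiles_canonical = canonical_smiles(smiles)
    )
    for (t in task_names) {
      match_t <- vapply(out$smiles_canonical, task_rule_match,
                        logical(1), smarts = spec$tasks[[t]], spec = spec,
                        USE.NAMES = FALSE)
      lab <- as.numeric(match_t)
      if (spec$noise > 0) {
        flip <- stats::runif(length(lab)) < spec$noise
        lab[flip] <- 1 - lab[flip]
      }
      if (spec$missing > 0) {
        lab[stats::runif(length(lab)) < spec$missing] <- NA_real_
      }
      out[[t]] <- lab
    }
    new_mol_dataset(out, task_names) |>
      structure(synth_spec = spec)
  })
}

# Families of repeat-unit molecules structurally disjoint from the base
# grammar and large enough to sit far from it in fingerprint space:
# polyphosphates (dense acceptor/anionic pharmacophores), long
# perfluoroalkyl chains (dense hydrophobic pairs), and siloxane repeats.
.od_families <- list(
  phosphonate = list(
    tails = c("CO", "CCO", "COCCO"),
    units = c("P(=O)(O)OCC", "P(=O)(O)OCCC", "P(=O)(OC)OCC"),
    ends = c("OP(=O)(O)O", "OP(=O)(O)OC", "O"),
    repeats = 2:5
  ),
  perfluoro = list(
    tails = c("FC(F)(F)", "FC(F)(F)C(F)(F)"),
    units = c("C(F)(F)", "C(F)(F)C(F)(F)"),
    ends = c("C(F)(F)F", "C(F)(F)C(F)(F)F"),
    repeats = 3:7
  ),
  silane = list(
    tails = c("C[Si](C)(C)", "CC[Si](C)(C)", "CCC[Si](C)(C)"),
    units = c("O[Si](C)(C)", "O[Si](C)(CC)", "O[Si](CC)(CC)"),
    ends = c("C", "CC", "O[Si](C)(C)C"),
    repeats = 5:9
  )
)

#' Generate an out-of-domain probe set
#'
#' Builds molecules exclusively from a fragment family disjoint from the
#' base grammar (phosphonates, perfluoroalkyls, or siloxanes/silanes), so
#' they are structurally distant from [generate_molecules()] output in
#' fingerprint space. Labels are assigned by the same task rules (typically
#' all negative) with no noise or masking.
#'
#' @param spec A [synth_spec()]; `n`, `tasks` and `seed` are used.
#' @param shift Family name: one of `"phosphonate"`, `"perfluoro"`,
#'   `"silane"`.
#' @return A molecule dataset tibble.
#' @export
generate_od_probe <- function(spec, shift) {
  stopifnot(inherits(spec, "synth_spec"))
  if (missing(shift) || is.null(shift) || !nzchar(shift)) {
    abort_fpgnn("shift must name a fragment family", "fpgnn_parameter_error")
  }
  fam <- .od_families[[shift]]
  if (is.null(fam)) {
    abort_fpgnn(paste0("unknown shift family: ", shift, " (available: ",
                       paste(names(.od_families), collapse = ", "), ")"),
                "fpgnn_parameter_error")
  }
  task_names <- names(spec$tasks)
  with_seed(derive_seed(spec$seed, "od", shift), {
    seen <- character(0); smiles <- character(0); tries <- 0
    while (length(smiles) < spec$n && tries < 50 * spec$n) {
      tries <- tries + 1
      r <- sample(fam$repeats, 1)
      s <- paste0(
        fam$tails[sample.int(length(fam$tails), 1)],
        paste(fam$units[sample.int(length(fam$units), r, replace = TRUE)],
              collapse = ""),
        fam$ends[sample.int(length(fam$ends), 1)]
      )
      can <- canonical_smiles(s)
      if (is.na(can) || can %in% seen) next
      seen <- c(seen, can)
      smiles <- c(smiles, s)
    }
    if (length(smiles) < spec$n) {
      warning("family grammar exhausted: generated ", length(smiles),
              " unique probe molecules of ", spec$n, " requested",
              call. = FALSE)
    }
    out <- tibble::tibble(
      id = sprintf("odp_%05d", seq_along(smiles)),
      smiles = smiles,
      smiles_canonical = canonical_smiles(smiles)
    )
    for (t in task_names) {
      m <- vapply(out$smiles_canonical, function(s2) {
        cnt <- smarts_count(s2, spec$tasks[[t]])
        as.numeric(!is.na(cnt) && cnt >= 1)
      }, numeric(1), USE.NAMES = FALSE)
      out[[t]] <- m
    }
    new_mol_dataset(out, task_names)
  })
}

#' Write a synthetic dataset with its spec sidecar
#'
#' Emits the CSV dialect read by [read_dataset()] plus a JSON sidecar
#' recording the generating spec.
#'
#' @param data Dataset from [generate_molecules()].
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.spec.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(data, path) {
  write_dataset(data, path)
  spec <- attr(data, "synth_spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".spec.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
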