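# Molecule parsing backend.
#
# All chemistry perception goes through OpenBabel (via ChemmineOB) and
# ChemmineR: SMILES validation and canonicalization, 2-D depiction
# coordinates, kekulized bond orders, and ring/aromaticity perception.
# Implicit hydrogen counts and hybridization are derived from the kekulized
# heavy-atom graph with a standard valence model. Parsed molecules are cached
# per session, keyed by the input SMILES string.

.fpgnn_cache <- new.env(parent = emptyenv())

cache_get <- function(store, key) {
  env <- .fpgnn_cache[[store]]
  if (is.null(env)) return(NULL)
  env[[key]]
}

cache_set <- function(store, key, value) {
  if (is.null(.fpgnn_cache[[store]])) {
    .fpgnn_cache[[store]] <- new.env(parent = emptyenv())
  }
  assign(key, value, envir = .fpgnn_cache[[store]])
  invisible(value)
}

#' Clear the molecule and feature caches
#'
#' Parsed molecules and computed features are memoised per session keyed by
#' SMILES. Call this to release memory or after changing a feature schema
#' option.
#'
#' @return Invisibly, `NULL`.
#' @export
clear_mol_cache <- function() {
  rm(list = ls(.fpgnn_cache), envir = .fpgnn_cache)
  invisible(NULL)
}

# Default valences used to infer implicit hydrogens on the kekulized
# heavy-atom graph. Charge shifts the target valence by its sign for N/O-like
# elements (ammonium 4, alkoxide 1, ...).
.default_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4, Se = 2
)

# MDL ctab charge codes: 1..7 -> +3,+2,+1,radical,-1,-2,-3
.mdl_charge <- c(3, 2, 1, 0, -1, -2, -3)

parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  hit <- cache_get("mol", smiles)
  if (!is.null(hit)) return(hit)

  info <- tryCatch(
    suppressWarnings(parse_smiles_impl(smiles)),
    error = function(e) list(valid = FALSE, smiles_input = smiles, error = conditionMessage(e))
  )
  cache_set("mol", smiles, info)
  info
}

parse_smiles_impl <- function(smiles) {
  can <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))
  can <- sub("[\t ].*$", "", sub("\n$", "", can))
  if (!nzchar(can)) {
    return(list(valid = FALSE, smiles_input = smiles, error = "unparsable SMILES"))
  }
  sdftxt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
  sdflines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1]]
  n_atoms <- as.integer(substr(sdflines[4], 1, 3))
  n_bonds_ctab <- as.integer(substr(sdflines[4], 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    return(list(valid = FALSE, smiles_input = smiles, error = "no atoms"))
  }
  if (n_bonds_ctab == 0) {
    # bond-free molecules (single heavy atom): ChemmineR rejects these, so
    # read the atom block directly
    al <- sdflines[4 + seq_len(n_atoms)]
    element <- trimws(substr(al, 32, 34))
    coords <- cbind(as.numeric(substr(al, 1, 10)), as.numeric(substr(al, 11, 20)))
    charge_code <- suppressWarnings(as.integer(substr(al, 37, 39)))
    charge_code[is.na(charge_code)] <- 0L
    sdf <- NULL
    bb <- NULL
  } else {
    sdf <- ChemmineR::read.SDFset(sdflines)[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    n_atoms <- nrow(ab)
    element <- sub("_.*$", "", rownames(ab))
    coords <- ab[, 1:2, drop = FALSE]
    charge_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, n_atoms)
  }
  charge <- ifelse(charge_code >= 1 & charge_code <= 7, .mdl_charge[pmax(charge_code, 1)], 0)
  # explicit M CHG lines override the atom-block charge codes
  chg_lines <- grep("^M  CHG", sdflines, value = TRUE)
  for (cl in chg_lines) {
    n_ent <- as.integer(substr(cl, 7, 9))
    for (e in seq_len(n_ent)) {
      off <- 10 + (e - 1) * 8
      at_i <- as.integer(substr(cl, off, off + 3))
      chg_v <- as.integer(substr(cl, off + 4, off + 7))
      if (!is.na(at_i) && at_i >= 1 && at_i <= n_atoms) charge[at_i] <- chg_v
    }
  }

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer(),
                            aromatic = logical(), in_ring = logical(),
                            conjugated = logical())
  } else {
    bonds <- tibble::tibble(
      i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  }

  # Ring and aromaticity perception (ChemmineR): a bond is aromatic when both
  # endpoints sit in one aromatic ring containing the bond.
  arom_atom <- rep(FALSE, n_atoms)
  ring_atom <- rep(FALSE, n_atoms)
  arom_bond <- rep(FALSE, nrow(bonds))
  ring_bond <- rep(FALSE, nrow(bonds))
  ring_tbl <- tibble::tibble(size = integer(), aromatic = logical(), hetero = logical())
  if (!is.null(sdf) && nrow(bonds) > 0 && n_atoms >= 3) {
    rg <- tryCatch(
      ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical())
    )
    for (ri in seq_along(rg$RINGS)) {
      members <- as.integer(sub("^.*_", "", rg$RINGS[[ri]]))
      ring_atom[members] <- TRUE
      on_ring <- bonds$i %in% members & bonds$j %in% members
      ring_bond <- ring_bond | on_ring
      if (isTRUE(rg$AROMATIC[[ri]])) {
        arom_atom[members] <- TRUE
        arom_bond <- arom_bond | on_ring
      }
      ring_tbl <- tibble::add_row(
        ring_tbl, size = length(members),
        aromatic = isTRUE(rg$AROMATIC[[ri]]),
        hetero = any(element[members] != "C")
      )
    }
  }

  degree <- tabulate(c(bonds$i, bonds$j), nbins = n_atoms)
  valence_sum <- numeric(n_atoms)
  if (nrow(bonds) > 0) {
    valence_sum <- segment_sum(rep(bonds$order, 2), c(bonds$i, bonds$j), n_atoms)
  }
  target <- unname(.default_valence[element])
  target[is.na(target)] <- valence_sum[is.na(target)]
  # charge raises the bonding capacity of N-like atoms and lowers it for
  # O-like anions; the symmetric rule charge*sign(lone-pair) collapses to +charge
  # for cations and -|charge| for anions of the organic subset
  target <- target + ifelse(element %in% c("N", "P"), charge,
                     ifelse(element %in% c("O", "S", "C"), -abs(charge), 0))
  # hypervalent S/P (sulfone, phosphate): expand to the observed valence
  target <- pmax(target, valence_sum)
  h_count <- pmax(0, round(target - valence_sum))

  max_order <- rep(1L, n_atoms)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      max_order[bonds$i[r]] <- max(max_order[bonds$i[r]], bonds$order[r])
      max_order[bonds$j[r]] <- max(max_order[bonds$j[r]], bonds$order[r])
    }
  }
  n_multi <- numeric(n_atoms)
  if (nrow(bonds) > 0) {
    multi <- bonds$order >= 2
    n_multi <- segment_sum(as.numeric(rep(multi, 2)), c(bonds$i, bonds$j), n_atoms)
  }
  hybrid <- ifelse(max_order >= 3 | n_multi >= 2, "sp",
            ifelse(max_order == 2 | arom_atom, "sp2", "sp3"))

  if (nrow(bonds) > 0) {
    unsat <- arom_atom | max_order >= 2
    bonds$aromatic <- arom_bond
    bonds$in_ring <- ring_bond
    bonds$conjugated <- arom_bond | (unsat[bonds$i] & unsat[bonds$j])
  }

  list(
    valid = TRUE,
    smiles_input = smiles,
    smiles_canonical = can,
    atoms = tibble::tibble(
      idx = seq_len(n_atoms), element = element, charge = as.numeric(charge),
      degree = degree, h_count = h_count, aromatic = arom_atom,
      in_ring = ring_atom, hybridization = hybrid
    ),
    bonds = bonds,
    rings = ring_tbl,
    coords = coords
  )
}

canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    info <- parse_smiles(s)
    if (isTRUE(info$valid)) info$smiles_canonical else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# OBMol handle for SMARTS matching / OpenBabel fingerprints, cached per SMILES.
ob_mol <- function(smiles) {
  hit <- cache_get("obmol", smiles)
  if (!is.null(hit)) return(hit)
  mol <- NULL
  ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), function(m) {
    mol <<- m
  })
  cache_set("obmol", smiles, mol)
  mol
}

smarts_count <- function(smiles, pattern) {
  mol <- ob_mol(smiles)
  if (is.null(mol)) return(NA_integer_)
  as.integer(ChemmineOB::smartsSearch_OB(list(mol), pattern))
}

# Minimal V2000 writer for scaffold canonicalization: we subset a parsed
# molecule to a set of atoms and ask OpenBabel for the canonical SMILES of
# the fragment. Coordinates are irrelevant for canonicalization.
fragment_canonical <- function(info, keep) {
  keep <- sort(keep)
  if (length(keep) == 0) return("")
  remap <- match(seq_len(nrow(info$atoms)), keep)
  b <- info$bonds[info$bonds$i %in% keep & info$bonds$j %in% keep, , drop = FALSE]
  at <- info$atoms[keep, , drop = FALSE]
  lines <- c(
    "", " fpgnn", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(at), nrow(b))
  )
  for (r in seq_len(nrow(at))) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, at$element[r]))
  }
  for (r in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", remap[b$i[r]], remap[b$j[r]],
                              if (b$aromatic[r]) 4L else b$order[r]))
  }
  chg <- which(at$charge != 0)
  if (length(chg) > 0) {
    lines <- c(lines, sprintf("M  CHG%3d%s", length(chg),
                              paste0(sprintf("%4d%4d", chg, at$charge[chg]), collapse = "")))
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(lines, collapse = "\n"), "\n"))),
    error = function(e) ""
  )
  sub("[\t ].*$", "", sub("\n$", "", out))
}
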