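# Molecular graph featurization for the graph-attention branch.
#
# The feature schema is fixed and versioned: changing it is a configuration
# change (new schema hash), never an implicit code change. Hydrogens are
# implicit: the graph covers heavy atoms only, with the hydrogen count as an
# atom feature.

.graph_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se", "other")
.graph_degrees <- 0:5          # capped at 5
.graph_charges <- -2:2         # capped at +/-2
.graph_hcounts <- 0:4          # capped at 4
.graph_hybrid <- c("sp", "sp2", "sp3")

#' Molecular graph feature schema
#'
#' Describes the atom and bond feature layout used by [mol_to_graph()]:
#' feature names in column order and the schema hash stored in checkpoints.
#'
#' @return A list with `atom_features`, `bond_features`, `d_atom`, `d_bond`
#'   and `hash`.
#' @export
graph_schema <- function() {
  atom_names <- c(
    paste0("elem_", .graph_elements),
    paste0("degree_", .graph_degrees),
    paste0("charge_", .graph_charges),
    paste0("hcount_", .graph_hcounts),
    paste0("hybrid_", .graph_hybrid),
    "aromatic", "in_ring"
  )
  bond_names <- c("order_1", "order_2", "order_3", "aromatic", "conjugated", "in_ring")
  list(
    atom_features = atom_names,
    bond_features = bond_names,
    d_atom = length(atom_names),
    d_bond = length(bond_names),
    hash = schema_hash(c("graph-v1", atom_names, bond_names))
  )
}

one_hot <- function(value, levels) {
  m <- matrix(0, length(value), length(levels))
  m[cbind(seq_along(value), match(value, levels))] <- 1
  m
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Builds the heavy-atom graph consumed by the graph-attention branch. Atom
#' features: element one-hot, degree, formal charge, implicit hydrogen count,
#' hybridization, aromaticity, ring membership. Bond features: bond order
#' one-hot, aromaticity, conjugation, ring membership. The full schema is
#' returned by [graph_schema()].
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph`: a list with `atom_features`
#'   (`n_atoms x d_atom` matrix), `bond_features` (`n_bonds x d_bond`),
#'   `bonds` (two-column integer matrix of undirected atom index pairs),
#'   `n_atoms`, `n_bonds` and `smiles_canonical`.
#' @examples
#' g <- mol_to_graph("CCO")
#' g$n_atoms  # 3
#' @export
mol_to_graph <- function(smiles) {
  info <- parse_smiles(smiles)
  if (!isTRUE(info$valid)) {
    abort_fpgnn(paste0("cannot featurize unparsable SMILES: ", smiles),
                "fpgnn_featurization_error")
  }
  key <- paste0("g:", info$smiles_canonical)
  hit <- cache_get("graph", key)
  if (!is.null(hit)) return(hit)

  at <- info$atoms
  elem <- ifelse(at$element %in% .graph_elements, at$element, "other")
  X <- cbind(
    one_hot(elem, .graph_elements),
    one_hot(pmin(at$degree, max(.graph_degrees)), .graph_degrees),
    one_hot(pmin(pmax(at$charge, min(.graph_charges)), max(.graph_charges)), .graph_charges),
    one_hot(pmin(at$h_count, max(.graph_hcounts)), .graph_hcounts),
    one_hot(at$hybridization, .graph_hybrid),
    as.numeric(at$aromatic),
    as.numeric(at$in_ring)
  )
  sch <- graph_schema()
  colnames(X) <- sch$atom_features

  b <- info$bonds
  if (nrow(b) > 0) {
    # aromatic bonds are their own type: the kekulized single/double
    # alternation must not leak into the features (ring symmetry)
    E <- cbind(
      one_hot(ifelse(b$aromatic, 0L, pmin(b$order, 3L)), 1:3),
      as.numeric(b$aromatic),
      as.numeric(b$conjugated),
      as.numeric(b$in_ring)
    )
    colnames(E) <- sch$bond_features
    pairs <- cbind(b$i, b$j)
  } else {
    E <- matrix(0, 0, sch$d_bond, dimnames = list(NULL, sch$bond_features))
    pairs <- matrix(integer(), 0, 2)
  }

  g <- structure(
    list(
      atom_features = X, bond_features = E, bonds = pairs,
      n_atoms = nrow(X), n_bonds = nrow(E),
      smiles_canonical = info$smiles_canonical,
      elements = at$element,
      coords = info$coords
    ),
    class = "mol_graph"
  )
  cache_set("graph", key, g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles_canonical, ": ", x$n_atoms, " atoms, ",
      x$n_bonds, " bonds\n", sep = "")
  invisible(x)
}

# Stack molecular graphs into one disjoint batch graph with directed edges
# (both directions per bond) plus one self-loop per atom, pre-sorted by
# destination atom so attention softmax groups are contiguous.
batch_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offset <- c(0L, cumsum(n_atoms))[seq_along(graphs)]
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  mol_of_atom <- rep(seq_along(graphs), n_atoms)
  N <- nrow(X)
  d_bond <- graph_schema()$d_bond

  src <- dst <- integer(0)
  bf_rows <- list()
  for (m in seq_along(graphs)) {
    g <- graphs[[m]]
    if (g$n_bonds > 0) {
      i <- g$bonds[, 1] + offset[m]
      j <- g$bonds[, 2] + offset[m]
      src <- c(src, i, j)
      dst <- c(dst, j, i)
      bf_rows[[length(bf_rows) + 1]] <- rbind(g$bond_features, g$bond_features)
    }
  }
  # self-loops with zero bond features
  src <- c(src, seq_len(N))
  dst <- c(dst, seq_len(N))
  EF <- rbind(
    if (length(bf_rows) > 0) do.call(rbind, bf_rows) else matrix(0, 0, d_bond),
    matrix(0, N, d_bond)
  )

  ord <- order(dst, src)
  src <- src[ord]; dst <- dst[ord]; EF <- EF[ord, , drop = FALSE]
  dst_idx <- split(seq_along(dst), dst)
  mol_idx <- split(seq_len(N), mol_of_atom)

  list(
    X = X, EF = EF, src = src, dst = dst,
    mol_of_atom = mol_of_atom, n_atoms = N, n_mols = length(graphs),
    dst_idx = dst_idx, mol_idx = mol_idx
  )
}
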