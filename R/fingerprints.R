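# Mixed molecular fingerprints for the fingerprint branch and the
# applicability domain: MACCS (166 keys), a PubChem-style 881-slot
# substructure key set, and a pharmacophore ErG descriptor. Concatenation
# order is fixed: [MACCS | PubChem | ErG].

.fp_lengths <- c(maccs = 166L, pubchem = 881L, erg = 315L)

#' Mixed fingerprint layout
#'
#' @return A named integer vector with the block lengths of the concatenated
#'   fingerprint, in concatenation order: MACCS (166), PubChem (881),
#'   ErG (315).
#' @export
fingerprint_lengths <- function() .fp_lengths

# ---------------------------------------------------------------------------
# MACCS

# OpenBabel evaluates the SMARTS-expressible MACCS keys; key 125 (more than
# one aromatic ring) is count-based and not SMARTS-expressible, so it is
# computed here from the cyclomatic number of the aromatic subgraph.
maccs_fp <- function(smiles) {
  info <- parse_smiles(smiles)
  if (!isTRUE(info$valid)) {
    abort_fpgnn(paste0("cannot fingerprint unparsable SMILES: ", smiles),
                "fpgnn_featurization_error")
  }
  mol <- ob_mol(smiles)
  bits <- ChemmineOB::fingerprint_OB(list(mol), "MACCS")[1:166]
  n_arom_atoms <- sum(info$atoms$aromatic)
  n_arom_bonds <- sum(info$bonds$aromatic)
  if (n_arom_atoms > 0 && n_arom_bonds > 0) {
    # aromatic ring count = cyclomatic number of the aromatic subgraph
    # (bonds - atoms + components), on aromatic atoms only
    arom_ids <- which(info$atoms$aromatic)
    el <- cbind(match(info$bonds$i[info$bonds$aromatic], arom_ids),
                match(info$bonds$j[info$bonds$aromatic], arom_ids))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n_arom_atoms) {
      g <- igraph::add_vertices(g, n_arom_atoms - igraph::vcount(g))
    }
    comps <- igraph::count_components(g)
    n_rings <- n_arom_bonds - n_arom_atoms + comps
    if (n_rings >= 2) bits[125] <- 1
  }
  as.integer(bits)
}

# ---------------------------------------------------------------------------
# PubChem-style 881-slot substructure keys
#
# The CACTVS-style layout is followed in spirit: a block of element counts,
# a block of ring counts, a block of bonded element-pair counts, and a block
# of SMARTS substructure keys. This table is the ground truth definition of
# the fingerprint; slots without an assigned rule are fixed at zero and
# reported as "unassigned".

pubchem_rules <- function() {
  hit <- cache_get("tables", "pubchem")
  if (!is.null(hit)) return(hit)

  ec <- function(idx, elem, n) tibble::tibble(
    local_index = idx, rule = "element_count", definition = elem,
    threshold = n, description = sprintf(">= %d %s", n, elem))
  rc <- function(idx, what, n) tibble::tibble(
    local_index = idx, rule = "ring_count", definition = what,
    threshold = n, description = sprintf(">= %d %s ring(s)", n, what))
  pr <- function(idx, pair, n, lab) tibble::tibble(
    local_index = idx, rule = "pair", definition = pair,
    threshold = n, description = lab)
  sm <- function(idx, smarts, lab, n = 1) tibble::tibble(
    local_index = idx, rule = "smarts", definition = smarts,
    threshold = n, description = lab)

  tab <- dplyr::bind_rows(
    # --- element count block (slots 1-60) ---
    ec(1, "H", 4), ec(2, "H", 8), ec(3, "H", 16), ec(4, "H", 32),
    ec(5, "C", 2), ec(6, "C", 4), ec(7, "C", 8), ec(8, "C", 16), ec(9, "C", 32),
    ec(10, "N", 1), ec(11, "N", 2), ec(12, "N", 4), ec(13, "N", 8),
    ec(14, "O", 1), ec(15, "O", 2), ec(16, "O", 4), ec(17, "O", 8), ec(18, "O", 16),
    ec(19, "S", 1), ec(20, "S", 2), ec(21, "S", 4),
    ec(22, "P", 1), ec(23, "P", 2), ec(24, "P", 4),
    ec(25, "F", 1), ec(26, "F", 2), ec(27, "F", 4),
    ec(28, "Cl", 1), ec(29, "Cl", 2), ec(30, "Br", 1), ec(31, "Br", 2),
    ec(32, "I", 1), ec(33, "B", 1), ec(34, "Si", 1), ec(35, "Se", 1),

    # --- ring count block (slots 116-180) ---
    rc(116, "size3", 1), rc(117, "size3", 2),
    rc(120, "size4", 1), rc(121, "size4", 2),
    rc(124, "size5", 1), rc(125, "size5", 2), rc(126, "size5", 3),
    rc(130, "size6", 1), rc(131, "size6", 2), rc(132, "size6", 3), rc(133, "size6", 4),
    rc(138, "size7", 1), rc(139, "size7", 2), rc(142, "size8", 1),
    rc(145, "any", 1), rc(146, "any", 2), rc(147, "any", 3), rc(148, "any", 4),
    rc(150, "aromatic", 1), rc(151, "aromatic", 2), rc(152, "aromatic", 3),
    rc(153, "aromatic", 4),
    rc(160, "hetero", 1), rc(161, "hetero", 2), rc(162, "hetero", 3),
    rc(165, "saturated", 1), rc(166, "saturated", 2),

    # --- bonded element-pair block (slots 264-340) ---
    pr(264, "C~C", 1, "C-C bond"), pr(265, "C~N", 1, "C-N bond"),
    pr(266, "C~O", 1, "C-O bond"), pr(267, "C~S", 1, "C-S bond"),
    pr(268, "C~P", 1, "C-P bond"), pr(269, "C~F", 1, "C-F bond"),
    pr(270, "C~Cl", 1, "C-Cl bond"), pr(271, "C~Br", 1, "C-Br bond"),
    pr(272, "C~I", 1, "C-I bond"), pr(273, "N~O", 1, "N-O bond"),
    pr(274, "N~N", 1, "N-N bond"), pr(275, "S~O", 1, "S-O bond"),
    pr(276, "P~O", 1, "P-O bond"), pr(277, "N~S", 1, "N-S bond"),
    pr(280, "C=C", 1, "C=C double bond"), pr(281, "C=O", 1, "C=O double bond"),
    pr(282, "C=N", 1, "C=N double bond"), pr(283, "N=O", 1, "N=O double bond"),
    pr(284, "C#C", 1, "C#C triple bond"), pr(285, "C#N", 1, "C#N triple bond"),
    pr(288, "c:c", 1, "aromatic C-C bond"), pr(289, "c:n", 1, "aromatic C-N bond"),
    pr(292, "C~C", 8, ">= 8 C-C bonds"), pr(293, "C~O", 2, ">= 2 C-O bonds"),
    pr(294, "C~O", 4, ">= 4 C-O bonds"), pr(295, "C~N", 2, ">= 2 C-N bonds"),

    # --- substructure SMARTS block (slots 341-881) ---
    sm(341, "[CX4H3]", "methyl group"),
    sm(342, "[CX4H2]", "methylene group"),
    sm(343, "[CX4H1]", "methine group"),
    sm(344, "[CX4H0]", "quaternary-substituted carbon"),
    sm(347, "[CX3]=[CX3]", "alkene"),
    sm(348, "[CX2]#[CX2]", "alkyne"),
    sm(351, "[OX2H]", "hydroxyl"),
    sm(352, "[OX2H][CX4]", "aliphatic alcohol"),
    sm(353, "[OX2H]c", "phenol"),
    sm(354, "[OX2]([#6])[#6]", "ether"),
    sm(355, "[CX3]=[OX1]", "carbonyl"),
    sm(356, "[CX3H1]=[OX1]", "aldehyde"),
    sm(357, "[#6][CX3](=[OX1])[#6]", "ketone"),
    sm(358, "[CX3](=[OX1])[OX2H1]", "carboxylic acid"),
    sm(359, "[CX3](=[OX1])[OX2][#6]", "ester"),
    sm(360, "[CX3](=[OX1])[NX3]", "amide"),
    sm(361, "[NX3;H2;!$(N=*)][#6]", "primary amine"),
    sm(362, "[NX3;H1]([#6])[#6]", "secondary amine"),
    sm(363, "[NX3;H0]([#6])([#6])[#6]", "tertiary amine"),
    sm(364, "[$([NX3](=O)=O),$([NX3+](=O)[O-])]", "nitro group"),
    sm(365, "[CX2]#[NX1]", "nitrile"),
    sm(366, "[NX3][NX3]", "hydrazine fragment"),
    sm(367, "N=N", "azo fragment"),
    sm(368, "[NX3][CX3](=[OX1])[NX3]", "urea"),
    sm(369, "[NX3][CX3](=[NX2])[NX3]", "guanidine"),
    sm(370, "[SX2H]", "thiol"),
    sm(371, "[SX2]([#6])[#6]", "thioether"),
    sm(372, "[SX4](=[OX1])(=[OX1])", "sulfonyl"),
    sm(373, "[SX4](=[OX1])(=[OX1])[NX3]", "sulfonamide"),
    sm(374, "[SX4](=[OX1])(=[OX1])[OX2H]", "sulfonic acid"),
    sm(375, "[PX4](=[OX1])", "phosphoryl"),
    sm(376, "[PX4](=[OX1])([OX2])[OX2]", "phosphate ester fragment"),
    sm(380, "[CX4]([F])([F])[F]", "trifluoromethyl"),
    sm(381, "c[F]", "fluorine on aromatic ring"),
    sm(382, "c[Cl]", "chlorine on aromatic ring"),
    sm(383, "c[Br]", "bromine on aromatic ring"),
    sm(384, "c[I]", "iodine on aromatic ring"),
    sm(390, "c1ccccc1", "benzene ring"),
    sm(391, "c1ccncc1", "pyridine ring"),
    sm(392, "c1cc[nH]c1", "pyrrole ring"),
    sm(393, "c1ccoc1", "furan ring"),
    sm(394, "c1ccsc1", "thiophene ring"),
    sm(395, "c1ccc2ccccc2c1", "naphthalene system"),
    sm(396, "c1ncncn1", "triazine ring"),
    sm(397, "c1cncnc1", "pyrimidine ring"),
    sm(400, "[#6]1[#6][#6][#6][#6][#6]1", "six-membered carbocycle"),
    sm(401, "[NX3R]", "ring nitrogen (non-aromatic)"),
    sm(402, "[OX2R]", "ring oxygen (non-aromatic)"),
    sm(403, "[SX2R]", "ring sulfur (non-aromatic)"),
    sm(410, "[#6](~[#6])(~[#1])(~[#8])~[#8]", "C(~C)(~H)(~O)(~O)"),
    sm(411, "[#6](~[#6])(~[#6])(~[#6])~[#7]", "C(~C)(~C)(~C)(~N)"),
    sm(412, "[#6](~[#7])~[#8]", "C(~N)(~O)"),
    sm(413, "[#7](~[#6])(~[#6])~[#6]", "N(~C)(~C)(~C)"),
    sm(414, "[#8]=[#6]~[#6]=[#8]", "O=C-C=O fragment"),
    sm(420, "[OX2H][CX4][CX4][OX2H]", "1,2-diol fragment"),
    sm(421, "[NX3][CX4][CX3](=[OX1])", "alpha-amino carbonyl"),
    sm(422, "c-[NX3]", "aniline-type nitrogen"),
    sm(423, "c-[OX2]", "aryl ether oxygen"),
    sm(424, "c-[CX3](=[OX1])", "aryl carbonyl"),
    sm(425, "c-[SX4](=[OX1])(=[OX1])", "aryl sulfonyl")
  )
  tab$global_index <- tab$local_index + .fp_lengths[["maccs"]]
  cache_set("tables", "pubchem", tab)
  tab
}

#' The PubChem-style substructure key table
#'
#' The definition of the 881-slot substructure fingerprint computed by
#' [mixed_fingerprint()]. Slots follow a CACTVS-style layout: element counts,
#' ring counts, bonded element-pair counts, and SMARTS substructure keys.
#' Slots not listed carry no rule and are always zero.
#'
#' @return A tibble with columns `local_index`, `global_index` (position in
#'   the concatenated mixed fingerprint), `rule`, `definition`, `threshold`
#'   and `description`.
#' @export
pubchem_key_table <- function() pubchem_rules()

pubchem_fp <- function(smiles) {
  info <- parse_smiles(smiles)
  if (!isTRUE(info$valid)) {
    abort_fpgnn(paste0("cannot fingerprint unparsable SMILES: ", smiles),
                "fpgnn_featurization_error")
  }
  tab <- pubchem_rules()
  bits <- integer(.fp_lengths[["pubchem"]])

  elem_counts <- table(info$atoms$element)
  elem_counts["H"] <- sum(info$atoms$h_count)
  ring_count <- function(what) {
    r <- info$rings
    switch(what,
      any = nrow(r),
      aromatic = sum(r$aromatic),
      hetero = sum(r$hetero),
      saturated = sum(!r$aromatic & !r$hetero & r$size >= 3),
      # sizeN
      sum(r$size == as.integer(sub("size", "", what)))
    )
  }
  pair_count <- function(def) {
    b <- info$bonds
    if (nrow(b) == 0) return(0L)
    el <- info$atoms$element
    op <- substr(def, 2, 2)
    e1 <- toupper(substr(def, 1, 1))
    e2raw <- substr(def, 3, nchar(def))
    e2 <- if (nchar(e2raw) == 1) toupper(e2raw) else e2raw
    sel <- switch(op,
      "~" = rep(TRUE, nrow(b)),
      "=" = b$order == 2 & !b$aromatic,
      "#" = b$order == 3,
      ":" = b$aromatic
    )
    a <- el[b$i]; bb <- el[b$j]
    sum(sel & ((a == e1 & bb == e2) | (a == e2 & bb == e1)))
  }

  for (r in seq_len(nrow(tab))) {
    cnt <- switch(tab$rule[r],
      element_count = {
        v <- elem_counts[tab$definition[r]]
        if (is.na(v)) 0L else as.integer(v)
      },
      ring_count = ring_count(tab$definition[r]),
      pair = pair_count(tab$definition[r]),
      smarts = smarts_count(smiles, tab$definition[r])
    )
    if (!is.na(cnt) && cnt >= tab$threshold[r]) bits[tab$local_index[r]] <- 1L
  }
  bits
}

# ---------------------------------------------------------------------------
# Pharmacophore ErG descriptor
#
# Six pharmacophore properties are assigned per heavy atom by rule; the
# descriptor counts property pairs at topological (shortest-path) distances
# 1..15 with a fuzziness increment of 0.3 on the two neighbouring distance
# bins. The reduced-graph ring-collapse step of the original ErG formulation
# is intentionally not applied (documented limitation); distances are
# measured on the heavy-atom graph.

.erg_props <- c("Donor", "Acceptor", "Positive", "Negative", "Hydrophobic", "Aromatic")
.erg_dmax <- 15L
.erg_fuzz <- 0.3

erg_pairs <- function() {
  hit <- cache_get("tables", "erg_pairs")
  if (!is.null(hit)) return(hit)
  idx <- which(upper.tri(diag(6), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  out <- tibble::tibble(p1 = .erg_props[idx[, "row"]], p2 = .erg_props[idx[, "col"]])
  cache_set("tables", "erg_pairs", out)
  out
}

#' ErG bit meanings
#'
#' @return A tibble with one row per ErG descriptor position: `local_index`,
#'   `global_index` (position in the concatenated mixed fingerprint), the
#'   property pair, and the topological distance it counts.
#' @export
erg_bit_info <- function() {
  pairs <- erg_pairs()
  out <- tidyr::crossing(
    pair = seq_len(nrow(pairs)), distance = seq_len(.erg_dmax))
  out <- dplyr::arrange(out, .data$pair, .data$distance)
  out$local_index <- seq_len(nrow(out))
  out$p1 <- pairs$p1[out$pair]
  out$p2 <- pairs$p2[out$pair]
  out$global_index <- out$local_index + .fp_lengths[["maccs"]] + .fp_lengths[["pubchem"]]
  out$meaning <- sprintf("('%s', '%s', %d)", out$p1, out$p2, out$distance)
  out[, c("local_index", "global_index", "p1", "p2", "distance", "meaning")]
}

erg_atom_properties <- function(info) {
  at <- info$atoms
  b <- info$bonds
  n <- nrow(at)
  nb <- vector("list", n)
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      nb[[b$i[r]]] <- c(nb[[b$i[r]]], b$j[r])
      nb[[b$j[r]]] <- c(nb[[b$j[r]]], b$i[r])
    }
  }
  has_het_neighbor <- vapply(seq_len(n), function(i) {
    any(!at$element[nb[[i]]] %in% c("C", "H"))
  }, logical(1))
  # acidic oxygens: O-H single-bonded to a C or S that carries =O
  acidic_o <- rep(FALSE, n)
  if (nrow(b) > 0) {
    dbl_o <- at$element == "O" &
      vapply(seq_len(n), function(i) {
        any(vapply(nb[[i]], function(j) {
          any((b$i == i & b$j == j | b$i == j & b$j == i) & b$order == 2)
        }, logical(1)))
      }, logical(1))
    carbonyl_like <- vapply(seq_len(n), function(i) {
      at$element[i] %in% c("C", "S", "P") && any(dbl_o[nb[[i]]])
    }, logical(1))
    acidic_o <- at$element == "O" & at$h_count > 0 &
      vapply(seq_len(n), function(i) any(carbonyl_like[nb[[i]]]), logical(1))
  }
  cbind(
    Donor = at$element %in% c("N", "O") & at$h_count > 0,
    Acceptor = (at$element == "O" | (at$element == "N" & !(at$aromatic & at$h_count > 0))) &
      at$charge <= 0,
    Positive = at$charge > 0 |
      (at$element == "N" & !at$aromatic & at$hybridization == "sp3" & at$h_count >= 2),
    Negative = at$charge < 0 | acidic_o,
    Hydrophobic = (at$element == "C" & !has_het_neighbor) |
      at$element %in% c("F", "Cl", "Br", "I"),
    Aromatic = at$aromatic
  )
}

erg_fp <- function(smiles) {
  info <- parse_smiles(smiles)
  if (!isTRUE(info$valid)) {
    abort_fpgnn(paste0("cannot fingerprint unparsable SMILES: ", smiles),
                "fpgnn_featurization_error")
  }
  props <- erg_atom_properties(info)
  n <- nrow(info$atoms)
  out <- numeric(21 * .erg_dmax)
  if (n >= 2 && nrow(info$bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(info$bonds[, c("i", "j")]), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    D <- igraph::distances(g)
    pairs <- erg_pairs()
    for (pi in seq_len(nrow(pairs))) {
      a1 <- which(props[, pairs$p1[pi]])
      a2 <- which(props[, pairs$p2[pi]])
      if (length(a1) == 0 || length(a2) == 0) next
      d_sub <- D[a1, a2, drop = FALSE]
      if (pairs$p1[pi] == pairs$p2[pi]) {
        d_vals <- d_sub[upper.tri(d_sub)]
      } else {
        d_vals <- as.vector(d_sub)
      }
      d_vals <- d_vals[is.finite(d_vals) & d_vals >= 1 & d_vals <= .erg_dmax]
      if (length(d_vals) == 0) next
      base <- (pi - 1) * .erg_dmax
      for (d in d_vals) {
        out[base + d] <- out[base + d] + 1
        if (d > 1) out[base + d - 1] <- out[base + d - 1] + .erg_fuzz
        if (d < .erg_dmax) out[base + d + 1] <- out[base + d + 1] + .erg_fuzz
      }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Mixed fingerprint

#' Compute the mixed molecular fingerprint
#'
#' Concatenates the MACCS keys (166 bits), the PubChem-style substructure
#' keys (881 bits, defined by [pubchem_key_table()]), and the pharmacophore
#' ErG descriptor (315 nonnegative reals, defined by [erg_bit_info()]), in
#' that fixed order.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mixed_fp`: a list with `maccs`, `pubchem`,
#'   `erg`, and `concatenated` (numeric vector of length 1362).
#' @examples
#' fp <- mixed_fingerprint("c1ccccc1")
#' sum(fp$maccs)
#' @export
mixed_fingerprint <- function(smiles) {
  info <- parse_smiles(smiles)
  if (!isTRUE(info$valid)) {
    abort_fpgnn(paste0("cannot fingerprint unparsable SMILES: ", smiles),
                "fpgnn_featurization_error")
  }
  key <- paste0("fp:", info$smiles_canonical)
  hit <- cache_get("fp", key)
  if (!is.null(hit)) return(hit)
  maccs <- maccs_fp(smiles)
  pubchem <- pubchem_fp(smiles)
  erg <- erg_fp(smiles)
  out <- structure(
    list(
      maccs = maccs, pubchem = pubchem, erg = erg,
      concatenated = c(as.numeric(maccs), as.numeric(pubchem), erg),
      smiles_canonical = info$smiles_canonical
    ),
    class = "mixed_fp"
  )
  cache_set("fp", key, out)
  out
}

#' @export
print.mixed_fp <- function(x, ...) {
  cat("<mixed_fp> ", x$smiles_canonical, ": ", sum(x$maccs), " MACCS bits, ",
      sum(x$pubchem), " PubChem bits, ", sum(x$erg > 0), " ErG bins set\n", sep = "")
  invisible(x)
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles Character vector of SMILES strings (all must parse).
#' @return A numeric matrix, one row per molecule, 1362 columns in the fixed
#'   concatenation order.
#' @export
fingerprint_matrix <- function(smiles) {
  out <- matrix(0, length(smiles), sum(.fp_lengths))
  for (i in seq_along(smiles)) {
    out[i, ] <- mixed_fingerprint(smiles[i])$concatenated
  }
  rownames(out) <- names(smiles)
  out
}

#' Resolve the meaning of mixed fingerprint positions
#'
#' Maps global bit indices of the concatenated fingerprint to their family
#' (MACCS, PubChem, ErG), family-local index, and human-readable meaning.
#'
#' @param global_index Integer vector of positions in 1..1362.
#' @return A tibble with columns `global_index`, `family`, `local_index`,
#'   `meaning`.
#' @export
fp_bit_info <- function(global_index) {
  stopifnot(all(global_index >= 1), all(global_index <= sum(.fp_lengths)))
  n_m <- .fp_lengths[["maccs"]]; n_p <- .fp_lengths[["pubchem"]]
  ptab <- pubchem_rules()
  etab <- erg_bit_info()
  purrr::map_dfr(as.integer(global_index), function(gi) {
    if (gi <= n_m) {
      tibble::tibble(global_index = gi, family = "MACCS", local_index = gi,
                     meaning = sprintf("MACCS key %d", gi))
    } else if (gi <= n_m + n_p) {
      li <- gi - n_m
      hit <- ptab$description[ptab$local_index == li]
      tibble::tibble(global_index = gi, family = "PubChem", local_index = li,
                     meaning = if (length(hit)) hit else "unassigned slot")
    } else {
      li <- gi - n_m - n_p
      tibble::tibble(global_index = gi, family = "ErG", local_index = li,
                     meaning = etab$meaning[li])
    }
  })
}
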