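# Graph featurization. Atoms carry concatenated one-hot blocks for element,
# formal charge, heavy-atom degree, explicit and implicit valence, plus an
# aromaticity bit; bonds carry a bond-order one-hot and a ring bit. No
# further descriptors are used: richer chemistry is left for the network to
# learn from structure.

ELEMENT_LIST <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                  "Si", "Sn", "Se", "Mg", "Zn", "Li", "Na", "K", "Cu", "Pd")

#' Atom and bond feature schema
#'
#' @return A list with the block widths of the atom feature vector
#'   (element one-hot incl. "other", charge one-hot over -2..2, degree
#'   0..5, explicit valence 0..6, implicit valence 0..6, aromatic bit) and
#'   the bond feature vector (order one-hot over 1/1.5/2/3, ring bit).
#' @export
feature_schema <- function() {
  atom_blocks <- c(element = length(ELEMENT_LIST) + 1L, charge = 5L,
                   degree = 6L, explicit_valence = 7L,
                   implicit_valence = 7L, aromatic = 1L)
  bond_blocks <- c(order = 4L, in_ring = 1L)
  list(atom_blocks = atom_blocks, atom_width = sum(atom_blocks),
       bond_blocks = bond_blocks, bond_width = sum(bond_blocks))
}

one_hot <- function(idx, width) {
  v <- numeric(width)
  v[idx] <- 1
  v
}

#' Featurize the atoms of a molecular graph
#'
#' @param g A `mol_graph`.
#' @return Numeric matrix, one row per atom, following the atom block of
#'   [feature_schema()]. Elements outside the supported list fall into the
#'   trailing "other" bin.
#' @export
featurize_atoms <- function(g) {
  sc <- feature_schema()
  n <- n_atoms(g)
  deg <- atom_degree(g)
  expv <- bond_order_sum(g)
  X <- matrix(0, n, sc$atom_width)
  for (a in seq_len(n)) {
    e_idx <- match(g$elem[a], ELEMENT_LIST)
    if (is.na(e_idx)) e_idx <- length(ELEMENT_LIST) + 1L
    ch <- min(max(g$charge[a], -2L), 2L) + 3L          # -2..2 -> bin 1..5
    dg <- min(deg[a], 5L) + 1L
    ev <- min(expv[a], 6L) + 1L
    iv <- min(g$hcount[a], 6L) + 1L
    X[a, ] <- c(one_hot(e_idx, sc$atom_blocks[["element"]]),
                one_hot(ch, sc$atom_blocks[["charge"]]),
                one_hot(dg, sc$atom_blocks[["degree"]]),
                one_hot(ev, sc$atom_blocks[["explicit_valence"]]),
                one_hot(iv, sc$atom_blocks[["implicit_valence"]]),
                as.numeric(g$aromatic[a]))
  }
  X
}

#' Featurize the bonds of a molecular graph
#'
#' @param g A `mol_graph`.
#' @return Numeric matrix, one row per bond (aligned with `g$bonds`):
#'   bond-order one-hot over {1, 1.5, 2, 3} and a ring bit. Access is
#'   symmetric because bonds are undirected.
#' @export
featurize_bonds <- function(g) {
  sc <- feature_schema()
  nb <- nrow(g$bonds)
  E <- matrix(0, nb, sc$bond_width)
  if (nb == 0L) return(E)
  ring <- ring_bonds(g)
  orders <- c(1, 1.5, 2, 3)
  for (k in seq_len(nb)) {
    o_idx <- match(g$bonds$order[k], orders)
    if (is.na(o_idx)) stop("bond with order outside {1, 1.5, 2, 3}")
    E[k, ] <- c(one_hot(o_idx, 4L), as.numeric(ring[k]))
  }
  E
}

#' Build the single reactant graph for a reaction record
#'
#' All reactant and reagent species are merged into one disjoint-union
#' graph (no edges across species). Reagent atoms are present for
#' featurization and attention but flagged non-reactive, as are reactant
#' species contributing no heavy atom to the product.
#'
#' @param record A `reaction_record`, or a list with `reactants` /
#'   optionally `reagents_smiles` for unlabelled inputs.
#' @return A `mol_graph` with extra fields: `reactive` (per-atom flag),
#'   `X` (atom features), `E` (bond features).
#' @export
build_reactant_graph <- function(record) {
  g <- record$reactants
  n_react_species <- max(g$species)
  if (!is.null(record$reagents_smiles) && nzchar(record$reagents_smiles)) {
    g <- mol_union(g, smiles_to_graph(record$reagents_smiles))
  }
  mask <- record$reactive_mask
  if (is.null(mask)) mask <- rep(TRUE, n_react_species)
  sp_reactive <- c(mask, rep(FALSE, max(g$species) - n_react_species))
  g$reactive <- sp_reactive[g$species]
  g$X <- featurize_atoms(g)
  g$E <- featurize_bonds(g)
  g
}
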