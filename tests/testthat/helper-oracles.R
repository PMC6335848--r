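# Independent brute-force oracle for candidate enumeration: generate every
# subset of 1..max_edits changes, filter and canonicalize with the same
# chemistry primitives, deduplicate by canonical SMILES.
brute_force_candidates <- function(record, changes, max_edits) {
  K <- nrow(changes)
  smis <- character(0)
  n_subsets <- 0L
  for (sz in seq_len(min(max_edits, K))) {
    combos <- utils::combn(K, sz)
    for (ci in seq_len(ncol(combos))) {
      combo <- changes[combos[, ci], , drop = FALSE]
      if (anyDuplicated(paste(combo$i, combo$j))) next
      n_subsets <- n_subsets + 1L
      edits <- bond_changes(combo$i, combo$j, combo$order)
      g <- tryCatch(apply_edits(record$reactants, edits), error = function(e) NULL)
      if (is.null(g) || !valence_filter(g)) next
      edit_atoms <- match(unique(c(edits$i, edits$j)), g$map)
      smi <- tryCatch(canonical_product(g, edit_atoms), error = function(e) NULL)
      if (is.null(smi)) next
      orig_sp <- unique(record$reactants$species[match(unique(c(edits$i, edits$j)),
                                                       record$reactants$map)])
      orig <- mol_subgraph(record$reactants,
                          which(record$reactants$species %in% orig_sp))
      if (identical(smi, canonical_smiles(graph_to_smiles(orig)))) next
      smis <- c(smis, smi)
    }
  }
  list(smiles = sort(unique(smis)), n_subsets = n_subsets)
}
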