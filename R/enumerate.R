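# Focused enumeration of candidate products: all combinations of up to
# `max_edits` of the top-K predicted bond changes (pairwise-distinct atom
# pairs), applied to the reactants, filtered by valence and connectivity,
# deduplicated by canonical product SMILES, and ordered by the preliminary
# score (the sum of the combination's change likelihoods).

#' Upper bound on the number of enumerated candidates
#'
#' @param K Number of candidate bond changes drawn from.
#' @param max_edits Maximum changes per combination (1..5).
#' @return `sum_{i=1..max_edits} choose(K, i)`.
#' @export
candidate_count_bound <- function(K, max_edits) {
  stopifnot(K >= 1L, max_edits >= 1L, max_edits <= 5L)
  sum(choose(K, seq_len(max_edits)))
}

#' Valence and sanitization filter for candidate structures
#'
#' @param graph A `mol_graph` produced by [apply_edits()].
#' @return `TRUE` iff every atom's total bond order (explicit plus
#'   recomputed implicit hydrogens) is within its element's permitted
#'   valence and the structure canonicalizes (sanitizes) cleanly.
#' @export
valence_filter <- function(graph) {
  s <- bond_order_sum(graph)
  total <- s + graph$hcount
  if (any(total > max_valence(graph$elem, graph$charge))) return(FALSE)
  ok <- tryCatch({
    canonical_smiles(graph_to_smiles(graph))
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Enumerate candidate products from the top-K bond changes
#'
#' Every subset of 1..`max_edits` changes with pairwise-distinct atom pairs
#' is imposed on the reactants. Combinations that violate valence, fail
#' sanitization, or leave the reactants unchanged are dropped; survivors
#' are deduplicated by canonical product SMILES (keeping the highest
#' preliminary score) and sorted by preliminary score descending.
#'
#' @param record A `reaction_record` (only its reactant graph is used).
#' @param changes Ordered change table from [top_k_changes()].
#' @param max_edits Maximum changes per combination (<= 5).
#' @param log_domain Score combinations by the sum of log-likelihoods
#'   instead of raw likelihoods; unlike the raw sum, this penalizes
#'   supersets of a combination.
#' @return List of candidates, each a list with `edit_combo`,
#'   `product_smiles`, `preliminary_score`, `graph` (full edited graph),
#'   `edit_atoms`; plus attribute `"stats"` (n_subsets, n_valid, n_unique).
#' @export
enumerate_candidates <- function(record, changes, max_edits = 5L,
                                 log_domain = FALSE) {
  stopifnot(max_edits >= 1L, max_edits <= 5L)
  K <- nrow(changes)
  reactants <- record$reactants
  bound <- if (K >= 1L) candidate_count_bound(K, max_edits) else 0
  cands <- list()
  n_subsets <- 0L; n_valid <- 0L
  if (K >= 1L) {
    for (sz in seq_len(min(max_edits, K))) {
      combos <- utils::combn(K, sz)
      for (ci in seq_len(ncol(combos))) {
        rows <- combos[, ci]
        combo <- changes[rows, , drop = FALSE]
        pair_ids <- paste(combo$i, combo$j, sep = "_")
        if (anyDuplicated(pair_ids)) next  # one final order per atom pair
        n_subsets <- n_subsets + 1L
        edits <- bond_changes(combo$i, combo$j, combo$order)
        g <- tryCatch(apply_edits(reactants, edits), error = function(e) NULL)
        if (is.null(g)) next
        s <- bond_order_sum(g)
        if (any(s + g$hcount > max_valence(g$elem, g$charge))) next
        edit_atoms <- match(unique(c(edits$i, edits$j)), g$map)
        # canonicalization doubles as the sanitization gate
        smi <- tryCatch(canonical_product(g, edit_atoms), error = function(e) NULL)
        if (is.null(smi)) next
        # connectivity constraint: drop candidates with no net change
        orig_atoms <- which(reactants$species %in%
                              unique(reactants$species[match(unique(c(edits$i, edits$j)),
                                                             reactants$map)]))
        orig_smi <- tryCatch(canonical_smiles(graph_to_smiles(mol_subgraph(reactants, orig_atoms))),
                             error = function(e) NULL)
        if (!is.null(orig_smi) && identical(smi, orig_smi)) next
        n_valid <- n_valid + 1L
        cands[[length(cands) + 1L]] <- list(
          edit_combo = edits,
          product_smiles = smi,
          preliminary_score = if (log_domain) sum(log(pmax(combo$likelihood, 1e-12)))
                              else sum(combo$likelihood),
          final_score = NA_real_,
          rank = NA_integer_,
          graph = g,
          edit_atoms = edit_atoms
        )
      }
    }
  }
  stopifnot(n_subsets <= bound)
  # dedup by canonical product SMILES, keep highest preliminary score
  if (length(cands) > 0L) {
    smis <- vapply(cands, `[[`, character(1), "product_smiles")
    prelim <- vapply(cands, `[[`, numeric(1), "preliminary_score")
    keep <- integer(0)
    for (s in unique(smis)) {
      grp <- which(smis == s)
      keep <- c(keep, grp[which.max(prelim[grp])])
    }
    cands <- cands[keep]
    prelim <- prelim[keep]
    smis <- smis[keep]
    ordn <- order(-prelim, smis, method = "radix")
    cands <- cands[ordn]
  }
  attr(cands, "stats") <- data.frame(n_subsets = n_subsets, n_valid = n_valid,
                                     n_unique = length(cands))
  cands
}

#' Coverage of the recorded product among enumerated candidates
#'
#' For each K, the fraction of records whose recorded product exact-matches
#' at least one enumerated candidate, plus the mean candidate count per
#' record.
#'
#' @param model A trained `reactivity_model`.
#' @param records Evaluation records.
#' @param Ks Integer vector of K values (all >= 1).
#' @param max_edits Maximum changes per combination.
#' @return `data.frame` with columns `K`, `coverage`, `mean_candidates`.
#' @export
coverage_at_k <- function(model, records, Ks, max_edits = 5L) {
  if (any(Ks < 1L))
    stop(errorCondition("K values must be >= 1", class = c("rxn_config_error", "error")))
  Kmax <- max(Ks)
  tops <- lapply(records, function(rec) {
    sr <- score_record(model, rec)
    top_k_changes(sr$logits, sr$graph, Kmax)
  })
  res <- lapply(sort(Ks), function(K) {
    hit <- logical(length(records)); ncand <- numeric(length(records))
    for (ii in seq_along(records)) {
      ch <- tops[[ii]][seq_len(min(K, nrow(tops[[ii]]))), , drop = FALSE]
      cands <- enumerate_candidates(records[[ii]], ch, max_edits)
      ncand[ii] <- length(cands)
      truth <- records[[ii]]$product_smiles
      hit[ii] <- any(vapply(cands, function(cc)
        exact_match(cc$product_smiles, truth), logical(1)))
    }
    data.frame(K = K, coverage = mean(hit), mean_candidates = mean(ncand))
  })
  do.call(rbind, res)
}
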