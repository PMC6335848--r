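# Reaction SMILES I/O: parsing the "reactants>reagents>products" dialect,
# extracting ground-truth graph edits by diffing connectivity, and applying
# edit sets back onto reactant graphs.
#
# A graph edit (bond change) is an (atom, atom, new bond order) triple over
# atom-map ids, with order in {0, 1, 1.5, 2, 3}; order 0 removes the bond.

BOND_ORDERS <- c(0, 1, 1.5, 2, 3)
MAX_EDITS_TRAIN <- 5L

mapping_error <- function(msg) {
  stop(errorCondition(msg, class = c("rxn_mapping_error", "error")))
}
valence_error <- function(msg) {
  stop(errorCondition(msg, class = c("rxn_valence_error", "error")))
}

#' Construct a canonical bond-change table
#'
#' @param i,j Atom-map ids of the changed pair.
#' @param order New bond order, one of 0, 1, 1.5, 2, 3 (0 = bond removed).
#' @return A `data.frame` with columns `i`, `j`, `order`, normalized so
#'   `i < j` and sorted; duplicated pairs are an error.
#' @export
bond_changes <- function(i = integer(0), j = integer(0), order = numeric(0)) {
  stopifnot(length(i) == length(j), length(j) == length(order))
  if (any(i == j)) stop("bond change with identical atoms")
  if (!all(order %in% BOND_ORDERS))
    stop("bond order must be one of 0, 1, 1.5, 2, 3")
  lo <- pmin(i, j); hi <- pmax(i, j)
  d <- data.frame(i = as.integer(lo), j = as.integer(hi), order = as.numeric(order))
  d <- d[order(d$i, d$j, d$order), , drop = FALSE]
  rownames(d) <- NULL
  if (anyDuplicated(d[, c("i", "j")]))
    stop("bond changes must have pairwise distinct atom pairs")
  d
}

edit_key <- function(edits) paste(edits$i, edits$j, edits$order, sep = "_")

#' Extract graph edits by diffing reactant and product connectivity
#'
#' Returns the (i, j, new order) triples, over atom-map ids, where the bond
#' order in the product differs from the reactants. Bonds broken to atoms
#' absent from the product yield order-0 edits; pairs with both atoms absent
#' contribute nothing.
#'
#' @param reactants,product `mol_graph`s with atom maps; product maps must be
#'   a subset of reactant maps.
#' @return A bond-change `data.frame` (see [bond_changes()]).
#' @export
extract_edits <- function(reactants, product) {
  rmap <- reactants$map
  pmap <- product$map
  if (any(pmap == 0L))
    mapping_error("product contains an unmapped heavy atom")
  missing <- setdiff(pmap, rmap)
  if (length(missing) > 0L)
    mapping_error(sprintf("product map number(s) %s absent from reactants",
                          paste(missing, collapse = ", ")))
  r_idx <- match(pmap, rmap)  # product atom -> reactant atom

  ei <- integer(0); ej <- integer(0); eo <- numeric(0)
  seen <- character(0)
  push <- function(mi, mj, o) {
    lo <- min(mi, mj); hi <- max(mi, mj)
    key <- paste(lo, hi, sep = "_")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    ei <<- c(ei, lo); ej <<- c(ej, hi); eo <<- c(eo, o)
  }

  # bonds present in the product whose order differs (or absent) in reactants
  if (nrow(product$bonds) > 0L) {
    for (k in seq_len(nrow(product$bonds))) {
      pi <- product$bonds$i[k]; pj <- product$bonds$j[k]
      o_p <- product$bonds$order[k]
      ri <- r_idx[pi]; rj <- r_idx[pj]
      o_r <- bond_order_between(reactants, ri, rj)
      if (o_r != o_p) push(pmap[pi], pmap[pj], o_p)
    }
  }
  # reactant bonds broken or changed: product order 0 when pair unbonded
  # there, including bonds to atoms that left (one atom absent)
  p_of_map <- match(rmap, pmap)  # reactant atom -> product atom (NA if gone)
  if (nrow(reactants$bonds) > 0L) {
    for (k in seq_len(nrow(reactants$bonds))) {
      ri <- reactants$bonds$i[k]; rj <- reactants$bonds$j[k]
      if (rmap[ri] == 0L || rmap[rj] == 0L) next
      pi <- p_of_map[ri]; pj <- p_of_map[rj]
      if (is.na(pi) && is.na(pj)) next  # both atoms absent: no edit
      o_p <- if (is.na(pi) || is.na(pj)) 0 else bond_order_between(product, pi, pj)
      if (o_p != reactants$bonds$order[k]) push(rmap[ri], rmap[rj], o_p)
    }
  }
  bond_changes(ei, ej, eo)
}

#' Apply a set of graph edits to a reactant graph
#'
#' Replaces bond orders per the edit set, applies a small charge
#' neutralization rule set (halide release, alkoxide/ammonium gaining or
#' losing a bond), recomputes implicit hydrogens on touched atoms, and
#' checks valence.
#'
#' @param reactants A `mol_graph` with atom maps.
#' @param edits Bond-change `data.frame` over atom-map ids.
#' @return The edited `mol_graph` (all fragments retained; callers drop
#'   fragments per their retention policy).
#' @export
apply_edits <- function(reactants, edits) {
  g <- reactants
  if (nrow(edits) == 0L) return(g)
  if (anyDuplicated(edits[, c("i", "j")]))
    stop("edits must reference pairwise distinct atom pairs")
  ai <- match(edits$i, g$map)
  aj <- match(edits$j, g$map)
  if (anyNA(ai) || anyNA(aj))
    mapping_error("edit references a map number absent from the reactants")
  touched <- unique(c(ai, aj))
  bi <- g$bonds$i; bj <- g$bonds$j; bo <- g$bonds$order
  for (k in seq_len(nrow(edits))) {
    lo <- min(ai[k], aj[k]); hi <- max(ai[k], aj[k])
    hit <- which(bi == lo & bj == hi)
    if (edits$order[k] == 0) {
      if (length(hit) > 0L) { bi <- bi[-hit]; bj <- bj[-hit]; bo <- bo[-hit] }
    } else if (length(hit) > 0L) {
      bo[hit] <- edits$order[k]
    } else {
      bi <- c(bi, lo); bj <- c(bj, hi); bo <- c(bo, edits$order[k])
    }
  }
  g$bonds <- data.frame(i = bi, j = bj, order = bo)
  g$species <- graph_components(g)
  s <- bond_order_sum(g)
  # charge bookkeeping so edited structures sanitize
  for (a in touched) {
    e <- g$elem[a]; ch <- g$charge[a]
    if (e %in% c("F", "Cl", "Br", "I")) {
      if (ch == 0L && s[a] == 0L) g$charge[a] <- -1L       # displaced halide
      else if (ch == -1L && s[a] >= 1L) g$charge[a] <- 0L  # halide bound
    } else if (e == "O") {
      if (ch == -1L && s[a] >= 2L) g$charge[a] <- 0L       # alkoxide alkylated
    } else if (e == "N") {
      if (ch == 1L && s[a] <= 3L) g$charge[a] <- 0L        # ammonium released
      else if (ch == 0L && s[a] == 4L) g$charge[a] <- 1L   # quaternized
    }
  }
  g <- recompute_hydrogens(g, touched)
  over <- touched[s[touched] > max_valence(g$elem[touched], g$charge[touched])]
  if (length(over) > 0L)
    valence_error(sprintf(
      "edit gives atom %s (%s) total bond order %d exceeding its valence",
      over[1], g$elem[over[1]], s[over[1]]))
  g
}

#' Parse one atom-mapped reaction SMILES line
#'
#' Expects the `reactants>reagents>products` dialect with atom maps linking
#' reactant and product heavy atoms. Ground-truth edits are extracted by
#' graph diff; the per-species reactive mask records which species
#' contribute at least one heavy atom to the product.
#'
#' @param line A reaction SMILES string with exactly two `>` separators.
#' @return A `reaction_record` list: the three SMILES fields, parsed
#'   `reactants` and `product` graphs, `edits`, `reactive_mask` (one flag
#'   per reactant species), and flags `no_reaction` / `too_many_edits`.
#' @export
parse_reaction <- function(line) {
  n_sep <- nchar(gsub("[^>]", "", line))
  if (n_sep != 2L)
    smiles_error("reaction must contain exactly two '>' separators", line)
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  parts <- c(parts, rep("", 3L - length(parts)))
  reactants_smiles <- parts[1]
  reagents_smiles <- parts[2]
  product_smiles <- parts[3]
  if (!nzchar(product_smiles))
    smiles_error("missing product field", line)
  reactants <- tryCatch(smiles_to_graph(reactants_smiles), error = function(e)
    smiles_error(sprintf("reactant fragment unparsable: %s", conditionMessage(e)), line))
  product <- tryCatch(smiles_to_graph(product_smiles), error = function(e)
    smiles_error(sprintf("product fragment unparsable: %s", conditionMessage(e)), line))
  if (nzchar(reagents_smiles)) {
    tryCatch(smiles_to_graph(reagents_smiles), error = function(e)
      smiles_error(sprintf("reagent fragment unparsable: %s", conditionMessage(e)), line))
  }
  edits <- extract_edits(reactants, product)
  pmaps <- product$map
  nsp <- max(reactants$species)
  mask <- vapply(seq_len(nsp), function(sp)
    any(reactants$map[reactants$species == sp] %in% pmaps), logical(1))
  rec <- list(
    reactants_smiles = reactants_smiles,
    reagents_smiles = reagents_smiles,
    product_smiles = product_smiles,
    reactants = reactants,
    product = product,
    edits = edits,
    reactive_mask = mask,
    no_reaction = nrow(edits) == 0L,
    too_many_edits = nrow(edits) > MAX_EDITS_TRAIN,
    meta = list()
  )
  class(rec) <- "reaction_record"
  rec
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record: %d reactant atoms, %d edits%s%s>\n",
              n_atoms(x$reactants), nrow(x$edits),
              if (x$no_reaction) ", no-reaction" else "",
              if (x$too_many_edits) ", >5 edits" else ""))
  invisible(x)
}

#' Reconstruct the recorded product by re-applying extracted edits
#'
#' Applies the record's edit set to its reactants and restricts the result
#' to the fragments holding atoms whose map ids occur in the recorded
#' product. Used by the round-trip validation law.
#'
#' @param record A `reaction_record`.
#' @return Canonical SMILES of the reconstructed product.
#' @export
reconstruct_product <- function(record) {
  g <- apply_edits(record$reactants, record$edits)
  keep_sp <- unique(g$species[g$map %in% record$product$map])
  sub <- mol_subgraph(g, which(g$species %in% keep_sp))
  canonical_smiles(graph_to_smiles(sub))
}

#' Read a reaction SMILES file
#'
#' One reaction per line; blank lines and `#` comments are skipped. Lines
#' that fail to parse are collected rather than aborting the read.
#'
#' @param path File path.
#' @return A list with `records` (list of `reaction_record`) and `errors`
#'   (data.frame of line numbers and messages).
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- list(); errs_line <- integer(0); errs_msg <- character(0)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s) || startsWith(s, "#")) next
    rec <- tryCatch(parse_reaction(s), error = function(e) e)
    if (inherits(rec, "error")) {
      errs_line <- c(errs_line, ln)
      errs_msg <- c(errs_msg, conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records,
       errors = data.frame(line = errs_line, message = errs_msg))
}

#' Write reaction records to a SMILES file
#' @param records List of `reaction_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(records, path) {
  lines <- vapply(records, function(r)
    paste(r$reactants_smiles, r$reagents_smiles, r$product_smiles, sep = ">"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

record_to_json <- function(record) {
  jsonlite::toJSON(list(
    reactants = record$reactants_smiles,
    reagents = record$reagents_smiles,
    product = record$product_smiles,
    edits = record$edits,
    reactive_mask = record$reactive_mask,
    no_reaction = record$no_reaction,
    too_many_edits = record$too_many_edits
  ), auto_unbox = TRUE, digits = NA)
}
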