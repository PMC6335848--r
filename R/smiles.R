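# Molecular graphs and the mapped-SMILES dialect.
#
# Molecules are held as plain attributed graphs: a vector of heavy atoms
# (element, formal charge, aromatic flag, hydrogen count, atom-map id,
# species/fragment id) plus a bond table (i, j, order) with i < j. Hydrogens
# are implicit throughout; atom-map ids attach only to heavy atoms. Aromatic
# bonds carry order 1.5.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")
# recognized element symbols (organic subset, common hetero/organometallic
# elements, and the usual counterion/catalyst metals)
KNOWN_ELEMENTS <- c(ORGANIC_SUBSET, "H", "Si", "Sn", "Se", "Mg", "Zn", "Li",
                    "Na", "K", "Ca", "Cu", "Pd", "Pt", "Ni", "Fe", "Mn", "Al",
                    "Cs", "Ag", "Au", "Ti", "Cr", "Co", "Hg", "Pb", "Bi", "*")

# Default (lowest standard) valence per element, adjusted for formal charge.
# Drives implicit-hydrogen assignment.
default_valence <- function(elem, charge = 0L) {
  base <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
            F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = 2)
  v <- unname(base[elem])
  v[is.na(v)] <- 0  # metals and exotic atoms get no implicit hydrogens
  # Charge shifts the bonding capacity: N+ binds 4, O- binds 1, C+/C- bind 3.
  shift <- ifelse(elem %in% c("N", "O", "P", "S", "B"), charge,
           ifelse(elem == "C", -abs(charge),
           ifelse(elem %in% c("F", "Cl", "Br", "I"), ifelse(charge < 0, charge, 0), 0)))
  pmax(0, v + shift)
}

# Maximum permitted total bond order (explicit + implicit H) used by the
# valence filter. Hypervalences common in organic chemistry are allowed
# (S up to 6, P up to 5); metals are treated permissively.
max_valence <- function(elem, charge = 0L) {
  base <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
            F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = 6)
  v <- unname(base[elem])
  v[is.na(v)] <- 8  # permissive for elements outside the table
  shift <- ifelse(elem %in% c("N", "O", "P", "S", "B"), charge,
           ifelse(elem == "C", -abs(charge),
           ifelse(elem %in% c("F", "Cl", "Br", "I"), ifelse(charge < 0, charge, 0), 0)))
  pmax(0, v + shift)
}

new_mol_graph <- function(elem, charge, aromatic, hcount, h_explicit, map, bonds) {
  n <- length(elem)
  g <- list(
    elem = as.character(elem),
    charge = as.integer(charge),
    aromatic = as.logical(aromatic),
    hcount = as.integer(hcount),
    h_explicit = as.logical(h_explicit),
    map = as.integer(map),
    species = integer(n),
    bonds = bonds
  )
  class(g) <- "mol_graph"
  g$species <- graph_components(g)
  g
}

#' Number of heavy atoms in a molecular graph
#' @param g A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) length(g$elem)

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph: %d atoms, %d bonds, %d species>\n",
              n_atoms(x), nrow(x$bonds), max(c(0L, x$species))))
  invisible(x)
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = numeric(0))
}

# Connected components (species ids), 1-based, in order of first atom.
# Plain BFS: molecules are tiny and this sits on the enumeration hot path.
graph_components <- function(g) {
  n <- n_atoms(g)
  if (n == 0L) return(integer(0))
  if (nrow(g$bonds) == 0L) return(seq_len(n))
  nbr <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (root in seq_len(n)) {
    if (comp[root] > 0L) next
    cur <- cur + 1L
    queue <- root
    comp[root] <- cur
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in nbr[[a]]) {
        if (comp[b] == 0L) { comp[b] <- cur; queue <- c(queue, b) }
      }
    }
  }
  comp
}

# Logical vector over bonds: TRUE when the bond lies on a cycle (not a bridge).
ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j), directed = FALSE)
  br <- igraph::bridges(ig)
  res <- rep(TRUE, nb)
  res[as.integer(br)] <- FALSE
  res
}

# Per-atom total explicit bond order; aromatic orders (1.5) summed then floored.
bond_order_sum <- function(g) {
  n <- n_atoms(g)
  s <- numeric(n)
  if (nrow(g$bonds) > 0L) {
    agg <- rowsum(c(g$bonds$order, g$bonds$order), c(g$bonds$i, g$bonds$j))
    s[as.integer(rownames(agg))] <- agg[, 1L]
  }
  as.integer(floor(s + 1e-9))
}

# Heavy-atom degree.
atom_degree <- function(g) {
  n <- n_atoms(g)
  d <- integer(n)
  if (nrow(g$bonds) > 0L) {
    t1 <- tabulate(g$bonds$i, nbins = n)
    t2 <- tabulate(g$bonds$j, nbins = n)
    d <- t1 + t2
  }
  d
}

# Recompute implicit hydrogen counts for the given atoms from the current
# bond table (used after graph edits).
recompute_hydrogens <- function(g, atoms = seq_len(n_atoms(g))) {
  s <- bond_order_sum(g)
  for (a in atoms) {
    v <- default_valence(g$elem[a], g$charge[a])
    g$hcount[a] <- max(0L, as.integer(v) - s[a])
    g$h_explicit[a] <- FALSE
  }
  g
}

# ---------------------------------------------------------------------------
# SMILES parsing

smiles_error <- function(msg, smiles) {
  stop(errorCondition(sprintf("%s (in SMILES %s)", msg, smiles),
                      class = c("rxn_format_error", "error")))
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with hydrogen counts, formal
#' charges and atom-map ids, aromatic (lowercase) atoms, ring closures
#' (including `%nn`), branches and dot-separated fragments. Stereo markers
#' are tolerated and discarded. Implicit hydrogen counts are assigned from
#' standard charge-adjusted valences.
#'
#' @param smiles A SMILES string.
#' @return A `mol_graph`.
#' @export
smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    smiles_error("empty or non-string SMILES", smiles)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  np <- length(chars)
  elem <- character(0); charge <- integer(0); aromatic <- logical(0)
  hcount <- integer(0); h_explicit <- logical(0); map <- integer(0)
  bi <- integer(0); bj <- integer(0); bord <- numeric(0)
  prev <- 0L           # index of previous atom (0 = none, e.g. after '.')
  pend <- NA_real_     # pending bond order symbol
  stack <- integer(0)  # branch stack
  ring <- list()       # open ring closures: num -> c(atom, order)
  pos <- 1L

  add_atom <- function(e, ch, ar, hc, hx, mp) {
    elem[length(elem) + 1L] <<- e
    charge[length(charge) + 1L] <<- ch
    aromatic[length(aromatic) + 1L] <<- ar
    hcount[length(hcount) + 1L] <<- hc
    h_explicit[length(h_explicit) + 1L] <<- hx
    map[length(map) + 1L] <<- mp
    idx <- length(elem)
    if (prev > 0L) {
      o <- pend
      if (is.na(o)) o <- if (aromatic[prev] && ar) 1.5 else 1
      bi[length(bi) + 1L] <<- min(prev, idx)
      bj[length(bj) + 1L] <<- max(prev, idx)
      bord[length(bord) + 1L] <<- o
    }
    prev <<- idx
    pend <<- NA_real_
    idx
  }

  close_ring <- function(num) {
    if (prev == 0L) smiles_error("ring closure with no open atom", smiles)
    key <- as.character(num)
    if (!is.null(ring[[key]])) {
      op <- ring[[key]]
      o <- pend
      if (is.na(o)) o <- op[["order"]]
      if (is.na(o)) o <- if (aromatic[op[["atom"]]] && aromatic[prev]) 1.5 else 1
      a <- op[["atom"]]
      if (a == prev) smiles_error("ring closure onto the same atom", smiles)
      bi[length(bi) + 1L] <<- min(a, prev)
      bj[length(bj) + 1L] <<- max(a, prev)
      bord[length(bord) + 1L] <<- o
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <<- list(atom = prev, order = pend)
    }
    pend <<- NA_real_
  }

  while (pos <= np) {
    ch <- chars[pos]
    if (ch == "[") {
      close_idx <- pos
      while (close_idx <= np && chars[close_idx] != "]") close_idx <- close_idx + 1L
      if (close_idx > np) smiles_error("unterminated bracket atom", smiles)
      body <- paste(chars[(pos + 1L):(close_idx - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)(se|si|[A-Z][a-z]?|b|c|n|o|p|s|\\*)(@{0,2}H?[0-9]*)?(H[0-9]*)?([+-][0-9+-]*)?(:([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0L) smiles_error(sprintf("cannot parse bracket atom [%s]", body), smiles)
      sym <- m[3]
      ar <- sym %in% AROMATIC_ELEMS || sym %in% c("se", "si")
      e <- if (ar && nchar(sym) <= 2L) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2))
      } else sym
      if (!(e %in% KNOWN_ELEMENTS))
        smiles_error(sprintf("unknown element symbol '%s'", e), smiles)
      # hydrogen count may appear inside the stereo blob or on its own
      hblob <- paste0(m[4], m[5])
      hc <- 0L
      hm <- regmatches(hblob, regexec("H([0-9]*)", hblob))[[1]]
      if (length(hm) > 0L) hc <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      chg <- 0L
      if (nzchar(m[6])) {
        cs <- m[6]
        if (grepl("^[+-][0-9]+$", cs)) {
          chg <- as.integer(paste0(substr(cs, 1, 1), sub("^[+-]", "", cs)))
          if (substr(cs, 1, 1) == "-") chg <- -abs(chg)
          else chg <- abs(chg)
        } else {
          chg <- sum(strsplit(cs, "")[[1]] == "+") - sum(strsplit(cs, "")[[1]] == "-")
        }
      }
      mp <- if (nzchar(m[8] %||% "")) as.integer(m[8]) else 0L
      add_atom(e, chg, ar, hc, TRUE, mp)
      pos <- close_idx + 1L
    } else if (ch %in% c("C", "B") && pos < np && chars[pos + 1L] %in% c("l", "r") &&
               paste0(ch, chars[pos + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[pos + 1L]), 0L, FALSE, 0L, FALSE, 0L)
      pos <- pos + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, 0L, FALSE, 0L, FALSE, 0L)
      pos <- pos + 1L
    } else if (ch %in% AROMATIC_ELEMS) {
      add_atom(toupper(ch), 0L, TRUE, 0L, FALSE, 0L)
      pos <- pos + 1L
    } else if (ch == "-") { pend <- 1; pos <- pos + 1L
    } else if (ch == "=") { pend <- 2; pos <- pos + 1L
    } else if (ch == "#") { pend <- 3; pos <- pos + 1L
    } else if (ch == ":") { pend <- 1.5; pos <- pos + 1L
    } else if (ch %in% c("/", "\\")) { pend <- 1; pos <- pos + 1L
    } else if (ch == "(") { stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_error("unbalanced parenthesis", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") { prev <- 0L; pend <- NA_real_; pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); pos <- pos + 1L
    } else if (ch == "%") {
      if (pos + 2L > np) smiles_error("truncated %nn ring closure", smiles)
      close_ring(as.integer(paste0(chars[pos + 1L], chars[pos + 2L])))
      pos <- pos + 3L
    } else {
      smiles_error(sprintf("unexpected character '%s'", ch), smiles)
    }
  }
  if (length(stack) > 0L) smiles_error("unbalanced parenthesis", smiles)
  if (length(ring) > 0L) smiles_error("unclosed ring bond", smiles)
  if (length(elem) == 0L) smiles_error("no atoms", smiles)

  bonds <- data.frame(i = bi, j = bj, order = bord)
  if (anyDuplicated(bonds[, c("i", "j")]))
    smiles_error("duplicate bond between one atom pair", smiles)
  g <- new_mol_graph(elem, charge, aromatic, hcount, h_explicit, map, bonds)
  # implicit hydrogens for non-bracket atoms
  s <- bond_order_sum(g)
  free <- !g$h_explicit
  g$hcount[free] <- pmax(0L, as.integer(default_valence(g$elem[free], g$charge[free])) - s[free])
  g
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# ---------------------------------------------------------------------------
# SMILES writing (valid, not canonical; canonicalization is delegated to
# OpenBabel downstream)

# Does this atom need a bracket when written?
needs_bracket <- function(g, a, include_maps) {
  if (include_maps && g$map[a] > 0L) return(TRUE)
  if (g$charge[a] != 0L) return(TRUE)
  e <- g$elem[a]
  if (!(e %in% ORGANIC_SUBSET)) return(TRUE)
  # bare atoms re-derive implicit H from valence; bracket if that would differ
  s <- bond_order_sum(g)[a]
  implied <- max(0L, as.integer(default_valence(e, 0L)) - s)
  implied != g$hcount[a]
}

bond_symbol <- function(order, ar_i, ar_j) {
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 1.5) return(if (ar_i && ar_j) "" else ":")
  if (order == 1 && ar_i && ar_j) return("-")
  ""
}

#' Write a molecular graph as SMILES
#'
#' Produces a valid (not canonical) SMILES string; pass the result through
#' [canonical_smiles()] for a canonical form.
#'
#' @param g A `mol_graph`.
#' @param include_maps Write `:n` atom-map ids for mapped atoms.
#' @return A SMILES string.
#' @export
graph_to_smiles <- function(g, include_maps = FALSE) {
  n <- n_atoms(g)
  if (n == 0L) return("")
  nb <- nrow(g$bonds)
  adj <- vector("list", n)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      adj[[i]] <- rbind(adj[[i]], c(j, k))
      adj[[j]] <- rbind(adj[[j]], c(i, k))
    }
  }
  visited <- logical(n)
  edge_used <- logical(nb)
  ring_counter <- 0L
  ring_open <- vector("list", n)  # atom -> integer vector of ring digits to emit
  ring_bond_sym <- character(99)

  atom_token <- function(a) {
    e <- g$elem[a]
    ar <- g$aromatic[a]
    sym <- if (ar && tolower(e) %in% AROMATIC_ELEMS) tolower(e) else e
    if (!needs_bracket(g, a, include_maps)) return(sym)
    hc <- g$hcount[a]
    hs <- if (hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
    chg <- g$charge[a]
    cs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
          else sprintf("%+d", chg)
    ms <- if (include_maps && g$map[a] > 0L) paste0(":", g$map[a]) else ""
    paste0("[", sym, hs, cs, ms, "]")
  }

  # pre-pass: assign ring-closure digits to back edges via DFS
  back_edges <- integer(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    dfs_stack <- list(c(root, 0L))
    visited[root] <- TRUE
    while (length(dfs_stack) > 0L) {
      top <- dfs_stack[[length(dfs_stack)]]
      dfs_stack[[length(dfs_stack)]] <- NULL
      a <- top[1]
      nbrs <- adj[[a]]
      if (!is.null(nbrs)) {
        for (r in seq_len(nrow(nbrs))) {
          b <- nbrs[r, 1]; k <- nbrs[r, 2]
          if (edge_used[k]) next
          if (visited[b]) {
            edge_used[k] <- TRUE
            back_edges <- c(back_edges, k)
          } else {
            edge_used[k] <- TRUE
            visited[b] <- TRUE
            dfs_stack[[length(dfs_stack) + 1L]] <- c(b, k)
          }
        }
      }
    }
  }
  for (k in back_edges) {
    ring_counter <- ring_counter + 1L
    num <- ring_counter
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    ring_open[[i]] <- c(ring_open[[i]], num)
    ring_open[[j]] <- c(ring_open[[j]], num)
    ring_bond_sym[num] <- bond_symbol(g$bonds$order[k], g$aromatic[i], g$aromatic[j])
  }

  is_back <- logical(nb); is_back[back_edges] <- TRUE
  visited <- logical(n)
  out <- character(0)

  write_atom <- function(a) {
    visited[a] <<- TRUE
    out[length(out) + 1L] <<- atom_token(a)
    for (num in ring_open[[a]]) {
      tok <- if (num > 9L) paste0("%", num) else as.character(num)
      out[length(out) + 1L] <<- paste0(ring_bond_sym[num], tok)
    }
    nbrs <- adj[[a]]
    if (is.null(nbrs)) return(invisible())
    kids <- integer(0); kedge <- integer(0)
    for (r in seq_len(nrow(nbrs))) {
      b <- nbrs[r, 1]; k <- nbrs[r, 2]
      if (is_back[k] || visited[b]) next
      kids <- c(kids, b); kedge <- c(kedge, k)
    }
    if (length(kids) == 0L) return(invisible())
    for (t in seq_along(kids)) {
      b <- kids[t]; k <- kedge[t]
      if (visited[b]) next  # may have been reached via a ring in a sibling
      bs <- bond_symbol(g$bonds$order[k], g$aromatic[a], g$aromatic[b])
      last <- t == length(kids) || all(visited[kids[(t + 1L):length(kids)]])
      if (!last) out[length(out) + 1L] <<- "("
      out[length(out) + 1L] <<- bs
      write_atom(b)
      if (!last) out[length(out) + 1L] <<- ")"
    }
    invisible()
  }

  frags <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    out <- character(0)
    write_atom(root)
    frags <- c(frags, paste(out, collapse = ""))
  }
  paste(frags, collapse = ".")
}

# Subgraph on a set of atom indices (bonds restricted; indices remapped).
mol_subgraph <- function(g, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  idx <- match(seq_len(n_atoms(g)), atoms)  # old -> new
  keep <- g$bonds$i %in% atoms & g$bonds$j %in% atoms
  b <- g$bonds[keep, , drop = FALSE]
  b$i <- idx[b$i]; b$j <- idx[b$j]
  rownames(b) <- NULL
  new_mol_graph(g$elem[atoms], g$charge[atoms], g$aromatic[atoms],
                g$hcount[atoms], g$h_explicit[atoms], g$map[atoms], b)
}

# Disjoint union of two graphs; species ids recomputed.
mol_union <- function(g1, g2) {
  off <- n_atoms(g1)
  b2 <- g2$bonds
  b2$i <- b2$i + off; b2$j <- b2$j + off
  new_mol_graph(c(g1$elem, g2$elem), c(g1$charge, g2$charge),
                c(g1$aromatic, g2$aromatic), c(g1$hcount, g2$hcount),
                c(g1$h_explicit, g2$h_explicit), c(g1$map, g2$map),
                rbind(g1$bonds, b2))
}

# Current bond order between two atom indices (0 if unbonded).
bond_order_between <- function(g, i, j) {
  a <- min(i, j); b <- max(i, j)
  hit <- which(g$bonds$i == a & g$bonds$j == b)
  if (length(hit) == 0L) 0 else g$bonds$order[hit[1]]
}
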