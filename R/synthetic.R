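# Synthetic reaction families with known ground-truth edit sets. Each
# family draws decorated substrates from a small scaffold grammar, derives
# its edits programmatically from the parsed structures, constructs the
# recorded product by applying those edits (keeping every fragment that
# holds an edit atom), and emits an atom-mapped reaction SMILES line. The
# shapes emulated from real patent data: small reaction centers, spectator
# substituents, inert co-solvents, and reagent-conditional outcomes.

ALKYL_TAILS <- c("", "C", "CC", "CCC", "(C)C")
ALKYL_GROUPS <- c("C", "CC", "CCC", "CCCC", "C(C)C")
ARYL_PARA <- c("", "C", "F", "OC", "CC")
DISTRACTORS <- c("CCCCCC", "CCOCC", "CC#N", "c1ccc(C)cc1")

#' Names of the shipped synthetic reaction families
#' @return Character vector of family names.
#' @export
reaction_families <- function() {
  c("sn2", "esterification", "amide", "alkylation_base", "suzuki",
    "decarboxylation")
}

pick <- function(x) x[sample.int(length(x), 1L)]

# neighbors of atom a in graph g
nbrs <- function(g, a) {
  c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a])
}

# Build one reaction for a family; returns list(reactants_smiles (unmapped),
# reagents, edits over atom indices as (ai, aj, order), scaffold key).
compose_family <- function(family, reagent_conditional) {
  if (family == "sn2") {
    t1 <- pick(ALKYL_TAILS)
    nu <- pick(ALKYL_GROUPS)
    halide <- paste0("BrC", t1)
    alkoxide <- paste0("[O-]", nu)
    g <- smiles_to_graph(paste(halide, alkoxide, sep = "."))
    br <- which(g$elem == "Br")
    cc <- nbrs(g, br)[1]
    oo <- which(g$elem == "O" & g$charge == -1L)
    list(smiles = paste(halide, alkoxide, sep = "."), reagents = "[Na+]",
         edits_idx = data.frame(a = c(cc, cc), b = c(br, oo), order = c(0, 1)),
         scaffold = paste0("sn2:", t1))
  } else if (family == "esterification") {
    acid_r <- pick(c(ALKYL_GROUPS, "c1ccccc1"))
    alc <- paste0("OC", pick(ALKYL_TAILS))
    acid <- paste0("OC(=O)", acid_r)
    g <- smiles_to_graph(paste(acid, alc, sep = "."))
    sp2 <- max(g$species)
    o_acid <- 1L  # leading hydroxyl of the acid as written
    cb <- nbrs(g, o_acid)[1]
    o_alc <- which(g$elem == "O" & g$species == sp2)[1]
    list(smiles = paste(acid, alc, sep = "."), reagents = "OS(=O)(=O)O",
         edits_idx = data.frame(a = c(cb, cb), b = c(o_acid, o_alc), order = c(0, 1)),
         scaffold = paste0("ester:", acid_r))
  } else if (family == "amide") {
    acid_r <- pick(ALKYL_GROUPS)
    amine <- pick(c("NCC", "NC(C)C", "CNC", "NCc1ccccc1"))
    acid <- paste0("OC(=O)", acid_r)
    g <- smiles_to_graph(paste(acid, amine, sep = "."))
    sp2 <- max(g$species)
    o_acid <- 1L
    cb <- nbrs(g, o_acid)[1]
    nn <- which(g$elem == "N" & g$species == sp2)[1]
    list(smiles = paste(acid, amine, sep = "."), reagents = "",
         edits_idx = data.frame(a = c(cb, cb), b = c(o_acid, nn), order = c(0, 1)),
         scaffold = paste0("amide:", acid_r))
  } else if (family == "alkylation_base") {
    t1 <- pick(ALKYL_TAILS)
    m <- pick(c("OCCN", "OCCCN", "OCC(C)N"))
    halide <- paste0("BrC", t1)
    g <- smiles_to_graph(paste(halide, m, sep = "."))
    br <- which(g$elem == "Br")
    cc <- nbrs(g, br)[1]
    oo <- which(g$elem == "O" & g$hcount == 1L)
    nn <- which(g$elem == "N")
    with_base <- if (reagent_conditional) sample(c(TRUE, FALSE), 1L) else TRUE
    nucleophile <- if (with_base) oo else nn
    list(smiles = paste(halide, m, sep = "."),
         reagents = if (with_base) "[Na+].[OH-]" else "",
         edits_idx = data.frame(a = c(cc, cc), b = c(br, nucleophile), order = c(0, 1)),
         scaffold = paste0("alk:", m))
  } else if (family == "suzuki") {
    s1 <- pick(ARYL_PARA)
    s2 <- pick(ARYL_PARA)
    ar1 <- if (nzchar(s1)) paste0("Brc1ccc(", s1, ")cc1") else "Brc1ccccc1"
    ar2 <- if (nzchar(s2)) paste0("OB(O)c1ccc(", s2, ")cc1") else "OB(O)c1ccccc1"
    g <- smiles_to_graph(paste(ar1, ar2, sep = "."))
    br <- which(g$elem == "Br")
    c1 <- nbrs(g, br)[1]
    bb <- which(g$elem == "B")
    c2 <- Filter(function(a) g$elem[a] == "C", nbrs(g, bb))[1]
    list(smiles = paste(ar1, ar2, sep = "."),
         reagents = "O=C([O-])[O-].[Na+].[Na+]",
         edits_idx = data.frame(a = c(c1, bb, c1), b = c(br, c2, c2),
                                order = c(0, 0, 1)),
         scaffold = paste0("suzuki:", s1, "|", s2))
  } else if (family == "decarboxylation") {
    r <- pick(c("CC", "CCC", "C(C)C", "Cc1ccccc1", "CCc1ccccc1"))
    acid <- paste0("OC(=O)", r)
    g <- smiles_to_graph(acid)
    o_acid <- 1L
    cb <- nbrs(g, o_acid)[1]
    ca <- Filter(function(a) g$elem[a] == "C" && a != cb, nbrs(g, cb))[1]
    list(smiles = acid, reagents = "",
         edits_idx = data.frame(a = cb, b = ca, order = 0),
         scaffold = paste0("decarb:", r))
  } else {
    stop(sprintf("unknown reaction family '%s'", family))
  }
}

#' Generate a synthetic atom-mapped reaction dataset
#'
#' Draws reactions from the requested families, assigns map numbers 1..n
#' over the reactant atoms, constructs each recorded product by applying
#' the family's ground-truth edits (all fragments containing an edit atom
#' are kept in the product), and returns fully parsed records. With
#' `reagent_conditional = TRUE` the base-conditional alkylation family
#' yields O- versus N-alkylation depending on the presence of its base
#' token, so the same substrate pair maps to different products.
#'
#' @param families Character vector from [reaction_families()].
#' @param n Number of records.
#' @param seed RNG seed; output is deterministic per seed.
#' @param reagent_conditional Make the conditional family condition on its
#'   reagent token rather than always using the base.
#' @param distractor_prob Probability of appending an inert, non-reacting
#'   species to the reactant pool.
#' @return List of `reaction_record` with `meta$family` and
#'   `meta$scaffold`.
#' @export
generate_reactions <- function(families = reaction_families(), n = 100L,
                               seed = 1L, reagent_conditional = TRUE,
                               distractor_prob = 0.3) {
  stopifnot(n >= 1L)
  set.seed(seed)
  records <- vector("list", n)
  for (ii in seq_len(n)) {
    fam <- pick(families)
    comp <- compose_family(fam, reagent_conditional)
    smi <- comp$smiles
    if (stats::runif(1) < distractor_prob) smi <- paste(smi, pick(DISTRACTORS), sep = ".")
    g <- smiles_to_graph(smi)
    g$map <- seq_len(n_atoms(g))
    edits <- bond_changes(g$map[comp$edits_idx$a], g$map[comp$edits_idx$b],
                          comp$edits_idx$order)
    prod <- apply_edits(g, edits)
    edit_atoms <- match(unique(c(edits$i, edits$j)), prod$map)
    keep_sp <- unique(prod$species[edit_atoms])
    prod_sub <- mol_subgraph(prod, which(prod$species %in% keep_sp))
    line <- paste(graph_to_smiles(g, include_maps = TRUE), comp$reagents,
                  graph_to_smiles(prod_sub, include_maps = TRUE), sep = ">")
    rec <- parse_reaction(line)
    rec$meta <- list(family = fam, scaffold = comp$scaffold)
    records[[ii]] <- rec
  }
  records
}

#' Split records into train/validation/test sets
#'
#' @param records List of `reaction_record`.
#' @param fractions Length-3 numeric summing to 1.
#' @param seed RNG seed.
#' @param scaffold_split When `TRUE`, whole substrate scaffolds are
#'   assigned to one split, so no scaffold is shared between train and
#'   test.
#' @return List with `train`, `valid`, `test`.
#' @export
family_split <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                         scaffold_split = FALSE) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop(errorCondition("fractions must be length 3 and sum to 1",
                        class = c("rxn_config_error", "error")))
  set.seed(seed)
  n <- length(records)
  if (scaffold_split) {
    scaf <- vapply(records, function(r) r$meta$scaffold %||% "none", character(1))
    groups <- split(seq_len(n), scaf)
    groups <- groups[sample(length(groups))]
    sizes <- round(fractions * n)
    assign_split <- integer(n)
    filled <- c(0L, 0L, 0L)
    for (grp in groups) {
      tgt <- which.max((sizes - filled) / pmax(sizes, 1L))
      assign_split[grp] <- tgt
      filled[tgt] <- filled[tgt] + length(grp)
    }
    idx <- list(which(assign_split == 1L), which(assign_split == 2L),
                which(assign_split == 3L))
  } else {
    perm <- sample(n)
    n_train <- round(fractions[1] * n)
    n_valid <- round(fractions[2] * n)
    idx <- list(perm[seq_len(n_train)],
                perm[seq_len(n_valid) + n_train],
                perm[setdiff(seq_len(n), seq_len(n_train + n_valid))])
  }
  list(train = records[idx[[1]]], valid = records[idx[[2]]],
       test = records[idx[[3]]])
}
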