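# Reaction parsing, edit extraction by graph diff, and edit application.

test_that("an SN2 reaction parses to its two-edit set", {
  rec <- parse_reaction("[CH3:1][Br:2].[O-:3][CH3:4]>>[CH3:1][O:3][CH3:4]")
  expect_identical(rec$edits,
                   data.frame(i = c(1L, 1L), j = c(2L, 3L), order = c(0, 1)))
  expect_identical(rec$reactive_mask, c(TRUE, TRUE))
  expect_false(rec$no_reaction)
})

test_that("identity reactions are flagged no-reaction", {
  rec <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]")
  expect_identical(nrow(rec$edits), 0L)
  expect_true(rec$no_reaction)
})

test_that("product maps absent from the reactants raise a mapping error", {
  expect_error(parse_reaction("[CH3:1][Br:2]>>[CH3:1][O:9]C"),
               class = "rxn_mapping_error")
})

test_that("malformed reaction lines raise format errors", {
  expect_error(parse_reaction("CC>CC"), class = "rxn_format_error")
  expect_error(parse_reaction("C(C>>CC"), class = "rxn_format_error")
  expect_error(parse_reaction("CC>>"), class = "rxn_format_error")
})

test_that("edit extraction recovers hydrolysis and coupling edit sets", {
  # ester hydrolysis: break the C-O ester bond, bind the water oxygen
  r <- smiles_to_graph("[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]")
  p <- smiles_to_graph("[CH3:1][C:2](=[O:3])[OH:6]")
  expect_identical(extract_edits(r, p),
                   data.frame(i = c(2L, 2L), j = c(4L, 6L), order = c(0, 1)))
  # amide coupling: acid loses its hydroxyl, gains the amine nitrogen
  r <- smiles_to_graph("[OH:1][C:2](=[O:3])[CH3:4].[NH2:5][CH3:6]")
  p <- smiles_to_graph("[C:2](=[O:3])([CH3:4])[NH:5][CH3:6]")
  expect_identical(extract_edits(r, p),
                   data.frame(i = c(1L, 2L), j = c(2L, 5L), order = c(0, 1)))
  # identical graphs: empty set
  g <- smiles_to_graph("[CH3:1][OH:2]")
  expect_identical(nrow(extract_edits(g, g)), 0L)
})

test_that("pairs with both atoms absent from the product contribute no edit", {
  r <- smiles_to_graph("[CH3:1][O:2][CH3:3].[CH3:4][Br:5]")
  p <- smiles_to_graph("[CH3:1][O:2][CH3:3]")  # the whole halide left
  expect_identical(nrow(extract_edits(r, p)), 0L)
})

test_that("applying edits reproduces products and the empty set is identity", {
  rec <- parse_reaction("[CH3:1][Br:2].[O-:3][CH3:4]>>[CH3:1][O:3][CH3:4]")
  g <- apply_edits(rec$reactants, rec$edits)
  # ether plus displaced bromide
  expect_identical(canonical_smiles(graph_to_smiles(g)),
                   canonical_smiles("COC.[Br-]"))
  g0 <- apply_edits(rec$reactants, bond_changes())
  expect_identical(graph_to_smiles(g0), graph_to_smiles(rec$reactants))
})

test_that("edits exceeding an atom's valence raise a valence error", {
  g <- smiles_to_graph("[C:1]([CH3:2])([CH3:3])([CH3:4])[CH3:5].[CH3:6][Br:7]")
  expect_error(apply_edits(g, bond_changes(1L, 6L, 1)),
               class = "rxn_valence_error")
})

test_that("charge bookkeeping neutralizes alkoxides and releases halides", {
  g <- smiles_to_graph("[CH3:1][Br:2].[O-:3][CH3:4]")
  out <- apply_edits(g, bond_changes(c(1L, 1L), c(2L, 3L), c(0, 1)))
  expect_identical(out$charge[out$elem == "O"], 0L)
  expect_identical(out$charge[out$elem == "Br"], -1L)
  expect_identical(out$hcount[out$elem == "Br"], 0L)
})

test_that("extract_edits after apply_edits returns the edit set (round trip)", {
  set.seed(5)
  recs <- generate_reactions(n = 25L, seed = 31L)
  for (rec in recs) {
    edited <- apply_edits(rec$reactants, rec$edits)
    back <- extract_edits(rec$reactants, edited)
    expect_identical(back, rec$edits)
  }
})

test_that("reaction files round-trip through read/write and report errors", {
  recs <- generate_reactions(n = 6L, seed = 12L)
  f <- withr::local_tempfile(fileext = ".smi")
  write_reactions(recs, f)
  rd <- read_reactions(f)
  expect_length(rd$records, 6L)
  expect_identical(nrow(rd$errors), 0L)
  writeLines(c("not a smiles>>C", "[CH3:1][OH:2]>>[CH3:1][OH:2]"), f)
  rd <- read_reactions(f)
  expect_length(rd$records, 1L)
  expect_identical(rd$errors$line, 1L)
})
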