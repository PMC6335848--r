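# Focused candidate enumeration, valence filtering, and coverage. The
# brute-force oracle lives in helper-oracles.R.

test_that("the candidate count bound is the binomial sum", {
  expect_identical(candidate_count_bound(6, 2), 21)
  expect_identical(candidate_count_bound(10, 5), 637)
  expect_identical(candidate_count_bound(1, 5), 1)
  expect_identical(candidate_count_bound(8, 3), 8 + 28 + 56)
})

test_that("valence filtering rejects hypervalent atoms and keeps real ones", {
  expect_false(valence_filter(smiles_to_graph("C(C)(C)(C)(C)C")))
  expect_true(valence_filter(smiles_to_graph("C[N+](C)(C)C")))
  expect_true(valence_filter(smiles_to_graph("CC(=O)Oc1ccccc1")))
  expect_true(valence_filter(smiles_to_graph("OS(=O)(=O)O")))  # S(VI) allowed
})

test_that("enumeration matches the brute-force oracle on random records", {
  records <- generate_reactions(n = 20L, seed = 99L)
  m <- tiny_wln_model(seed = 8L)
  for (rec in records) {
    sr <- score_record(m, rec)
    K <- 8L
    changes <- top_k_changes(sr$logits, sr$graph, K)
    cands <- enumerate_candidates(rec, changes, max_edits = 5L)
    got <- sort(unique(vapply(cands, `[[`, character(1), "product_smiles")))
    oracle <- brute_force_candidates(rec, changes, max_edits = 5L)
    expect_identical(got, oracle$smiles)
    st <- attr(cands, "stats")
    expect_identical(st$n_subsets, oracle$n_subsets)
    expect_lte(st$n_subsets, candidate_count_bound(nrow(changes), 5L))
  }
})

test_that("subsets proposing two orders for one atom pair are skipped", {
  rec <- parse_reaction("[CH3:1][Br:2].[O-:3][CH3:4]>>[CH3:1][O:3][CH3:4]")
  changes <- data.frame(i = c(1L, 1L), j = c(3L, 3L), order = c(1, 2),
                        likelihood = c(0.9, 0.8))
  cands <- enumerate_candidates(rec, changes, max_edits = 2L)
  # only the two singletons survive; the conflicting pair subset is skipped
  expect_identical(attr(cands, "stats")$n_subsets, 2L)
})

test_that("candidates are deduplicated and sorted by preliminary score", {
  fix <- fixture_learning()
  rec <- fix$splits$test[[1]]
  sr <- score_record(fix$m1, rec)
  cands <- enumerate_candidates(rec, top_k_changes(sr$logits, sr$graph, 10L), 3L)
  smis <- vapply(cands, `[[`, character(1), "product_smiles")
  expect_identical(anyDuplicated(smis), 0L)
  prelim <- vapply(cands, `[[`, numeric(1), "preliminary_score")
  expect_true(all(diff(prelim) <= 1e-12))
  # preliminary score is exactly the sum of the combo's likelihoods
  ch <- top_k_changes(sr$logits, sr$graph, 10L)
  for (cc in cands[seq_len(min(3, length(cands)))]) {
    lik <- merge(cc$edit_combo, ch, by = c("i", "j", "order"))$likelihood
    expect_equal(cc$preliminary_score, sum(lik), tolerance = 1e-12)
  }
})

test_that("the true product appears among candidates when its edits are listed", {
  rec <- parse_reaction("[CH3:1][Br:2].[O-:3][CH3:4]>>[CH3:1][O:3][CH3:4].[Br-:2]")
  changes <- data.frame(i = c(1L, 1L, 2L, 3L),
                        j = c(2L, 3L, 4L, 4L),
                        order = c(0, 1, 1, 2),
                        likelihood = c(0.9, 0.8, 0.2, 0.1))
  cands <- enumerate_candidates(rec, changes, max_edits = 2L)
  hits <- vapply(cands, function(cc)
    exact_match(cc$product_smiles, rec$product_smiles), logical(1))
  expect_true(any(hits))
})

test_that("log-domain preliminary scores penalize superset combinations", {
  rec <- parse_reaction("[CH3:1][Br:2].[O-:3][CH3:4]>>[CH3:1][O:3][CH3:4].[Br-:2]")
  changes <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 4L),
                        order = c(0, 1, 1), likelihood = c(0.9, 0.8, 0.3))
  raw <- enumerate_candidates(rec, changes, max_edits = 3L)
  logd <- enumerate_candidates(rec, changes, max_edits = 3L, log_domain = TRUE)
  score_of <- function(cands, smi) {
    hit <- vapply(cands, function(cc) cc$product_smiles == smi, logical(1))
    cands[hit][[1]]$preliminary_score
  }
  # the two-edit SN2 product is a superset of the single bond cleavage:
  # raw sums rank the superset higher, log sums rank it lower
  expect_gt(score_of(raw, "COC.[Br-]"), score_of(raw, "C.[Br-]"))
  expect_lt(score_of(logd, "COC.[Br-]"), score_of(logd, "C.[Br-]"))
})

test_that("coverage is non-decreasing in K and rejects K = 0", {
  fix <- fixture_learning()
  test_recs <- fix$splits$test[1:25]
  cov <- coverage_at_k(fix$m1, test_recs, Ks = c(2L, 4L, 6L, 10L), max_edits = 3L)
  expect_true(all(diff(cov$coverage) >= 0))
  expect_true(all(cov$mean_candidates >= 0))
  expect_error(coverage_at_k(fix$m1, test_recs, Ks = c(0L, 2L)),
               class = "rxn_config_error")
})
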