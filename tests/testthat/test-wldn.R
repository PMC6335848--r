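# Difference-network ranking: representations, scores, losses, prediction.

test_that("an identity candidate yields the zero reaction representation", {
  m <- tiny_wln_model()
  rcfg <- wldn_config(hidden_dim = 8L, depth = 2L, seed = 5L)
  sc <- feature_schema()
  set.seed(5)
  params <- rxnwln:::wldn_init(rcfg, sc$atom_width, sc$bond_width)
  g <- rxnwln:::featurize_plain(smiles_to_graph("CC(=O)OC"))
  local <- wln_embed(g, params, rcfg$depth)
  dr <- difference_representation(local, local, params)
  expect_equal(dr$rep, rep(0, rcfg$hidden_dim))
})

test_that("mirror-equivalent edits on a symmetric substrate give equal representations", {
  rcfg <- wldn_config(hidden_dim = 8L, depth = 2L, seed = 6L)
  sc <- feature_schema()
  set.seed(6)
  params <- rxnwln:::wldn_init(rcfg, sc$atom_width, sc$bond_width)
  # 1,3-dibromopropane: breaking either terminal C-Br is symmetric
  r <- smiles_to_graph("[Br:1][CH2:2][CH2:3][CH2:4][Br:5]")
  g1 <- apply_edits(r, bond_changes(1L, 2L, 0))
  g2 <- apply_edits(r, bond_changes(4L, 5L, 0))
  lr <- wln_embed(rxnwln:::featurize_plain(r), params, rcfg$depth)
  l1 <- wln_embed(rxnwln:::featurize_plain(g1), params, rcfg$depth)
  l2 <- wln_embed(rxnwln:::featurize_plain(g2), params, rcfg$depth)
  d1 <- difference_representation(lr, l1, params)
  d2 <- difference_representation(lr, l2, params)
  expect_equal(d1$rep, d2$rep, tolerance = 1e-10)
})

test_that("the final score is the linear head plus the preliminary score", {
  rcfg <- wldn_config(hidden_dim = 6L, seed = 3L)
  set.seed(3)
  params <- list(wf = stats::runif(6), bf = 0.37)
  rep0 <- rep(0, 6)
  expect_equal(final_score(rep0, 1.25, params), 0.37 + 1.25)
  r <- stats::runif(6)
  base <- final_score(r, 2, params)
  expect_equal(final_score(r, 2 + 0.5, params), base + 0.5)  # shift linearity
  expect_equal(base, sum(r * params$wf) + params$bf + 2, tolerance = 1e-12)
})

test_that("the softmax ranking loss matches closed forms", {
  expect_equal(as.numeric(ranking_loss(rep(0, 4), 1L)), log(4), tolerance = 1e-12)
  expect_lt(as.numeric(ranking_loss(c(20, 0, 0), 1L)), 1e-8)
  expect_equal(as.numeric(ranking_loss(0, 1L)), 0)
  d <- attr(ranking_loss(c(1, 1), 2L), "dscores")
  expect_equal(sum(d), 0, tolerance = 1e-12)
})

test_that("batched candidate scoring equals the per-candidate scalar route", {
  fix <- fixture_learning()
  rec <- fix$splits$test[[2]]
  sr <- score_record(fix$m1, rec)
  cands <- enumerate_candidates(rec, top_k_changes(sr$logits, sr$graph, 8L), 2L)
  expect_gt(length(cands), 1L)
  prelims <- vapply(cands, `[[`, numeric(1), "preliminary_score")
  rg <- rxnwln:::featurize_plain(rec$reactants)
  cg <- lapply(cands, function(cc) rxnwln:::featurize_plain(cc$graph))
  p <- fix$m2$params; rcfg <- fix$m2$config
  fw <- rxnwln:::wldn_forward_record(rg, cg, prelims, p, rcfg)
  lr <- wln_embed(rg, p, rcfg$depth)
  for (ci in seq_along(cands)) {
    lc <- wln_embed(cg[[ci]], p, rcfg$depth)
    dr <- difference_representation(lr, lc, p)
    expect_equal(final_score(dr$rep, prelims[ci], p), fw$scores[ci],
                 tolerance = 1e-8)
  }
})

test_that("prediction returns normalized probabilities and ranked candidates", {
  fix <- fixture_learning()
  pred <- predict(fix$pipe, fix$splits$test[[1]])
  expect_false(pred$no_prediction)
  expect_equal(sum(pred$candidates$probability), 1, tolerance = 1e-6)
  expect_identical(pred$candidates$rank, seq_len(nrow(pred$candidates)))
  expect_true(all(diff(pred$candidates$final_score) <= 1e-12))
  expect_true(all(abs(rowSums(pred$attention) - 1) < 1e-6))
})

test_that("unmapped reactant input is mapped internally at predict time", {
  fix <- fixture_learning()
  pred <- predict(fix$pipe, "BrCC.[O-]CC", top_n = 3L)
  expect_false(pred$no_prediction)
  expect_lte(nrow(pred$candidates), 3L)
  expect_error(predict(fix$pipe, "BrC[CH3:1]"), class = "rxn_mapping_error")
})

test_that("zeroing the ranker head reduces ranking to preliminary order", {
  fix <- fixture_learning()
  m2z <- fix$m2
  m2z$params$wf <- m2z$params$wf * 0
  m2z$params$bf <- 0
  pipe0 <- rxn_pipeline(fix$m1, m2z)
  pipe_prelim <- rxn_pipeline(fix$m1, NULL)
  for (rec in fix$splits$test[1:8]) {
    a <- predict(pipe0, rec)
    b <- predict(pipe_prelim, rec)
    expect_identical(a$candidates$product_smiles, b$candidates$product_smiles)
    expect_equal(a$candidates$final_score, b$candidates$preliminary_score,
                 tolerance = 1e-12)
  }
})

test_that("top-k accuracy is monotone in k and handles empty predictions", {
  fix <- fixture_learning()
  acc <- topk_accuracy(fix$preds, fix$splits$test)
  expect_true(all(diff(acc$accuracy) >= 0))
  none <- structure(list(candidates = data.frame(), no_prediction = TRUE),
                    class = "ranked_prediction")
  acc0 <- topk_accuracy(list(none), fix$splits$test[1])
  expect_true(all(acc0$accuracy == 0))
  expect_error(topk_accuracy(list(none), fix$splits$test[1:2]),
               class = "rxn_data_error")
})
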