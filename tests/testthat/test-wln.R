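# WLN embedding, attention, pair scoring, losses, and training mechanics.

scored_toy <- function(smiles = "[CH3:1][CH2:2][Br:3].[O-:4][CH3:5]", seed = 42L) {
  rec <- parse_reaction(paste0(smiles, ">>", smiles))
  g <- build_reactant_graph(rec)
  m <- tiny_wln_model(seed)
  list(rec = rec, g = g, m = m,
       fw = rxnwln:::wln_forward(g, m$params, m$config))
}

test_that("an isolated atom's embedding depends only on its own features", {
  m <- tiny_wln_model()
  g1 <- build_reactant_graph(list(reactants = smiles_to_graph("[Na+]")))
  g2 <- build_reactant_graph(list(reactants = smiles_to_graph("[Na+].[Cl-]")))
  l1 <- wln_embed(g1, m$params, m$config$depth)
  l2 <- wln_embed(g2, m$params, m$config$depth)
  expect_equal(as.vector(l1[1, ]), as.vector(l2[1, ]), tolerance = 1e-12)
})

test_that("depth 0 is rejected", {
  expect_error(wln_config(depth = 0L), class = "rxn_config_error")
  m <- tiny_wln_model()
  g <- build_reactant_graph(list(reactants = smiles_to_graph("CC")))
  expect_error(wln_embed(g, m$params, 0L), class = "rxn_config_error")
})

test_that("attention rows are normalized and a single atom attends to itself", {
  s <- scored_toy()
  expect_true(all(abs(rowSums(s$fw$attention) - 1) < 1e-10))
  m <- tiny_wln_model()
  g1 <- build_reactant_graph(list(reactants = smiles_to_graph("[Na+]")))
  l1 <- wln_embed(g1, m$params, m$config$depth)
  at <- global_attention(l1, m$params, self_attention = TRUE)
  expect_equal(as.vector(at$attention), 1)
  expect_equal(as.vector(at$context), as.vector(l1[1, ]))
})

test_that("bond-change logits are exactly symmetric in (i, j)", {
  s <- scored_toy()
  expect_identical(s$fw$logits, aperm(s$fw$logits, c(2, 1, 3)))
})

test_that("atoms in disconnected identical fragments get equal score rows", {
  rec <- parse_reaction("[CH3:1][OH:2].[CH3:3][OH:4]>>[CH3:1][OH:2].[CH3:3][OH:4]")
  g <- build_reactant_graph(rec)
  m <- tiny_wln_model()
  fw <- rxnwln:::wln_forward(g, m$params, m$config)
  # atom 1 (first methyl C) and atom 3 (second methyl C) are equivalent
  expect_equal(fw$local[1, ], fw$local[3, ], tolerance = 1e-12)
  expect_equal(fw$logits[1, 2, ], fw$logits[3, 4, ], tolerance = 1e-10)
})

test_that("a single logit matches its unbatched scalar recomputation", {
  s <- scored_toy(seed = 7L)
  p <- s$m$params
  pav <- s$fw$local + s$fw$context
  u <- 2L; v <- 4L; o <- 3L
  q <- pmax(as.vector(pav[u, ] + pav[v, ]) %*% p$Wp + p$bp, 0)
  expect_equal(as.numeric(q %*% p$Wo[, o] + p$bo[o]), s$fw$logits[u, v, o],
               tolerance = 1e-10)
})

test_that("scores are equivariant under atom relabeling", {
  m <- tiny_wln_model()
  rec <- parse_reaction(
    "[OH:1][C:2](=[O:3])[CH3:4].[NH2:5][CH3:6]>>[C:2](=[O:3])([CH3:4])[NH:5][CH3:6]")
  g <- build_reactant_graph(rec)
  fw <- rxnwln:::wln_forward(g, m$params, m$config)
  set.seed(21)
  for (r in 1:3) {
    perm <- sample(n_atoms(g))
    gp <- permute_mol_graph(g, perm)
    gp$reactive <- g$reactive[perm]
    gp$X <- featurize_atoms(gp); gp$E <- featurize_bonds(gp)
    fwp <- rxnwln:::wln_forward(gp, m$params, m$config)
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    expect_equal(fwp$logits[inv, inv, ], fw$logits, tolerance = 1e-5)
    expect_equal(fwp$attention[inv, inv], fw$attention, tolerance = 1e-6)
  }
})

test_that("the sigmoid cross-entropy loss matches its closed forms", {
  mk <- function(z) {
    logits <- array(0, c(2, 2, 5)); labels <- array(0, c(2, 2, 5))
    mask <- array(FALSE, c(2, 2, 5))
    logits[1, 2, 1] <- z; mask[1, 2, 1] <- TRUE
    list(logits = logits, labels = labels, mask = mask)
  }
  x <- mk(0); x$labels[1, 2, 1] <- 1
  expect_equal(as.numeric(reactivity_loss(x$logits, x$labels, x$mask)), log(2),
               tolerance = 1e-12)
  x <- mk(20); x$labels[1, 2, 1] <- 1
  expect_equal(as.numeric(reactivity_loss(x$logits, x$labels, x$mask)),
               log1p(exp(-20)), tolerance = 1e-12)
  x <- mk(-20)  # label 0, strongly negative logit: near-zero loss
  expect_lt(as.numeric(reactivity_loss(x$logits, x$labels, x$mask)), 1e-8)
})

test_that("analytic gradients match finite differences on a 5-atom example", {
  set.seed(12)
  rec <- parse_reaction("[CH3:1][CH2:2][Br:3].[O-:4][CH3:5]>>[CH3:1][CH2:2][O:4][CH3:5]")
  g <- build_reactant_graph(rec)
  cfg <- wln_config(hidden_dim = 7L, depth = 2L, att_entropy = 0.05, seed = 3L)
  sc <- feature_schema()
  params <- rxnwln:::wln_init(cfg, sc$atom_width, sc$bond_width)
  tg <- rxnwln:::reactivity_targets(g, rec$edits)
  lossfn <- function(p) {
    fw <- rxnwln:::wln_forward(g, p, cfg)
    a <- pmax(fw$attention, 1e-12)
    as.numeric(reactivity_loss(fw$logits, tg$labels, tg$mask)) +
      cfg$att_entropy * sum(a * log(a))
  }
  rg <- rxnwln:::reactivity_record_grad(g, rec$edits, params, cfg)
  eps <- 1e-5
  for (nm in names(params)) {
    for (r in 1:3) {
      idx <- sample(length(params[[nm]]), 1)
      p1 <- params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
      p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
      num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      ana <- rg$grads[[nm]][idx]
      denom <- abs(num) + abs(ana)
      if (denom > 1e-6) {
        expect_lt(abs(num - ana) / denom, 1e-4, label = sprintf("%s[%d]", nm, idx))
      } else {
        expect_lt(abs(num - ana), 1e-6)
      }
    }
  }
})

test_that("top-K selection masks species, skips current orders, breaks ties", {
  rec <- parse_reaction("[CH3:1][Br:2].[O-:3][CH3:4]>[Na+]>[CH3:1][O:3][CH3:4]")
  g <- build_reactant_graph(rec)
  n <- n_atoms(g)
  logits <- array(-10, c(n, n, 5))
  logits[1, 2, 1] <- 5    # break C-Br: highest
  logits[1, 3, 2] <- 4    # form C-O
  logits[3, 4, 4] <- 3    # O=C on the methoxide
  top <- top_k_changes(logits, g, 3L)
  expect_identical(top$i, c(1L, 1L, 3L))
  expect_identical(top$j, c(2L, 3L, 4L))
  expect_identical(top$order, c(0, 1, 2))
  # existing order excluded: (1,2) single bond cannot be proposed as order 1
  logits2 <- array(-10, c(n, n, 5))
  logits2[1, 2, 2] <- 9
  top2 <- top_k_changes(logits2, g, 200L)
  expect_false(any(top2$i == 1L & top2$j == 2L & top2$order == 1))
  # equal likelihoods everywhere: deterministic (i, j, order) tie-break
  logits3 <- array(0, c(n, n, 5))
  top3 <- top_k_changes(logits3, g, 4L)
  expect_identical(top3$i, c(1L, 1L, 1L, 1L))
  expect_identical(top3$j, c(2L, 2L, 2L, 2L))
  expect_identical(top3$order, c(0, 1.5, 2, 3))
  expect_error(top_k_changes(logits3, g, 0L), class = "rxn_config_error")
})

test_that("masked species never appear in the top-K list", {
  # ethane is a mapped distractor contributing nothing to the product
  rec <- parse_reaction(
    "[CH3:1][Br:2].[O-:3][CH3:4].[CH3:5][CH3:6]>>[CH3:1][O:3][CH3:4]")
  g <- build_reactant_graph(rec)
  expect_identical(g$reactive, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  logits <- array(0, c(n_atoms(g), n_atoms(g), 5))
  top <- top_k_changes(logits, g, 1000L)
  expect_gt(nrow(top), 0L)
  expect_true(all(top$i %in% 1:4) && all(top$j %in% 1:4))
})

test_that("a true edit on a masked species is a data error", {
  rec <- parse_reaction(
    "[CH3:1][Br:2].[O-:3][CH3:4].[CH3:5][CH3:6]>>[CH3:1][O:3][CH3:4]")
  g <- build_reactant_graph(rec)
  bad <- bond_changes(1L, 5L, 1)  # edit touching the inert species
  expect_error(rxnwln:::reactivity_targets(g, bad), class = "rxn_data_error")
})

test_that("short training reduces the loss and is seed-reproducible", {
  recs <- generate_reactions("sn2", n = 24L, seed = 77L, distractor_prob = 0)
  cfg <- wln_config(hidden_dim = 12L, depth = 2L, K = 6L, max_edits = 2L,
                    epochs = 3L, batch_size = 8L, lr = 2e-3, seed = 5L)
  m <- train_reactivity(recs, cfg)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  m2 <- train_reactivity(recs, cfg)
  expect_identical(m$history, m2$history)
  expect_equal(m$params, m2$params)
})
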