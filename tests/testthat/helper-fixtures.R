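# Shared fixtures. The two trained pipelines are expensive, so they are
# memoized for the duration of the test run; every consumer sees the same
# models. Problem sizes: 500 two-family records for the learning fixture,
# 320 reagent-conditional records for the conditional fixture, hidden
# width 32 and depth 2 throughout.

.fixture_env <- new.env(parent = emptyenv())

# Small configs used by fast structural tests.
tiny_wln_config <- function(...) {
  wln_config(hidden_dim = 8L, depth = 2L, K = 8L, max_edits = 3L,
             epochs = 1L, seed = 42L, ...)
}

tiny_wln_model <- function(seed = 42L) {
  cfg <- tiny_wln_config()
  sc <- feature_schema()
  set.seed(seed)
  params <- rxnwln:::wln_init(cfg, sc$atom_width, sc$bond_width)
  structure(list(params = params, config = cfg), class = "reactivity_model")
}

# Reorder the atoms of a mol_graph by `perm` (new position k holds old atom
# perm[k]); used by permutation-invariance tests.
permute_mol_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- g$bonds
  i2 <- inv[b$i]; j2 <- inv[b$j]
  b2 <- data.frame(i = pmin(i2, j2), j = pmax(i2, j2), order = b$order)
  rxnwln:::new_mol_graph(g$elem[perm], g$charge[perm], g$aromatic[perm],
                         g$hcount[perm], g$h_explicit[perm], g$map[perm], b2)
}

# Learning fixture: SN2 + esterification, 500 records, two-stage training.
fixture_learning <- function() {
  if (!is.null(.fixture_env$learning)) return(.fixture_env$learning)
  records <- generate_reactions(c("sn2", "esterification"), n = 500L, seed = 2024L)
  splits <- family_split(records, c(0.8, 0.1, 0.1), seed = 7L)
  cfg <- wln_config(hidden_dim = 32L, depth = 2L, K = 10L, max_edits = 3L,
                    epochs = 25L, batch_size = 8L, lr = 2e-3, seed = 101L)
  m1 <- train_reactivity(splits$train, cfg, valid = splits$valid)
  rcfg <- wldn_config(hidden_dim = 32L, depth = 2L, epochs = 5L, lr = 2e-3,
                      batch_size = 8L, max_train_candidates = 10L, seed = 102L)
  m2 <- train_ranker(splits$train, m1, rcfg)
  pipe <- rxn_pipeline(m1, m2)
  preds <- lapply(splits$test, function(r) predict(pipe, r))
  .fixture_env$learning <- list(records = records, splits = splits,
                                m1 = m1, m2 = m2, pipe = pipe, preds = preds)
  .fixture_env$learning
}

# Reagent-conditional fixture: base-conditional alkylation family.
fixture_conditional <- function() {
  if (!is.null(.fixture_env$conditional)) return(.fixture_env$conditional)
  records <- generate_reactions("alkylation_base", n = 320L, seed = 4242L,
                                reagent_conditional = TRUE, distractor_prob = 0.2)
  splits <- family_split(records, c(0.85, 0.05, 0.1), seed = 9L)
  cfg <- wln_config(hidden_dim = 32L, depth = 2L, K = 10L, max_edits = 3L,
                    epochs = 35L, batch_size = 8L, lr = 2e-3, seed = 201L)
  m1 <- train_reactivity(splits$train, cfg, valid = splits$valid)
  # the ranker stays deliberately small here: its only job on this family
  # is to demote superset edit combinations, and a wider net memorizes
  # substrate-outcome pairs it cannot justify (it never sees the reagent)
  rcfg <- wldn_config(hidden_dim = 8L, depth = 2L, epochs = 4L, lr = 2e-3,
                      batch_size = 8L, max_train_candidates = 10L, seed = 202L)
  m2 <- train_ranker(splits$train, m1, rcfg)
  .fixture_env$conditional <- list(records = records, splits = splits,
                                   m1 = m1, m2 = m2, pipe = rxn_pipeline(m1, m2))
  .fixture_env$conditional
}
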