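# Weisfeiler-Lehman difference network: candidates and reactants are
# embedded with the same WLN trunk (separate parameters from the scoring
# network by default), the per-atom representation differences are pooled
# into a reaction representation, and a linear head plus the preliminary
# score yields the final candidate score. Softmax cross-entropy against the
# recorded outcome trains the ranker; softmax over final scores is the
# predicted probability distribution over products.

#' Ranker (WLDN) configuration
#'
#' @param hidden_dim Width of atom representations.
#' @param depth Message-passing iterations.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Records per gradient step.
#' @param max_train_candidates Cap on candidates per record during training
#'   (the true candidate is always kept; the rest are the highest
#'   preliminary scorers). `Inf` disables the cap.
#' @param share_embedder Initialize the trunk from the reactivity WLN's
#'   embedding parameters instead of fresh random values.
#' @param seed RNG seed.
#' @return A `wldn_config` list.
#' @export
wldn_config <- function(hidden_dim = 300L, depth = 3L, lr = 1e-3, epochs = 10L,
                        batch_size = 16L, max_train_candidates = 16L,
                        share_embedder = FALSE, seed = 1L) {
  if (depth < 1L)
    stop(errorCondition("depth must be >= 1", class = c("rxn_config_error", "error")))
  structure(list(hidden_dim = as.integer(hidden_dim), depth = as.integer(depth),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 max_train_candidates = max_train_candidates,
                 share_embedder = isTRUE(share_embedder), seed = as.integer(seed)),
            class = "wldn_config")
}

wldn_init <- function(config, atom_dim, bond_dim) {
  h <- config$hidden_dim
  trunk <- wln_init(config, atom_dim, bond_dim, scoring = FALSE)
  c(trunk, list(Wd = rand_mat(h, h), wf = stats::runif(h, -1, 1) / sqrt(h), bf = 0))
}

featurize_plain <- function(g) {
  g$X <- featurize_atoms(g)
  g$E <- featurize_bonds(g)
  g
}

#' Reaction representation of one candidate
#'
#' Per-atom differences between the candidate's and the reactants' local
#' WLN representations (the edited graph shares the reactants' atom
#' indexing), summed over atoms and passed through a bias-free ReLU layer.
#' An identity candidate therefore maps to the zero vector.
#'
#' @param reactant_local Local representation matrix of the reactant graph.
#' @param candidate_local Local representation matrix of the candidate graph.
#' @param params Ranker parameter list.
#' @return List with `rep` (length hidden_dim), and cache fields `pooled`,
#'   `pre`.
#' @export
difference_representation <- function(reactant_local, candidate_local, params) {
  stopifnot(nrow(reactant_local) == nrow(candidate_local))
  pooled <- colSums(candidate_local - reactant_local)
  pre <- as.vector(pooled %*% params$Wd)
  list(rep = relu(pre), pooled = pooled, pre = pre)
}

#' Final candidate score
#'
#' A linear head on the reaction representation, added to the candidate's
#' preliminary score (the sum of its bond-change likelihoods). The addition
#' is exact: zeroing the head reduces the final score to the preliminary
#' score.
#'
#' @param rep Reaction representation vector.
#' @param preliminary Preliminary score.
#' @param params Ranker parameter list (`wf`, `bf`).
#' @return Scalar score.
#' @export
final_score <- function(rep, preliminary, params) {
  sum(rep * params$wf) + params$bf + preliminary
}

#' Softmax cross-entropy ranking loss
#'
#' @param final_scores Numeric vector of candidate scores.
#' @param true_index Index of the recorded outcome among the candidates.
#' @return Scalar loss; attribute `"dscores"` holds its gradient
#'   (softmax minus one-hot).
#' @export
ranking_loss <- function(final_scores, true_index) {
  stopifnot(true_index >= 1L, true_index <= length(final_scores))
  smax <- max(final_scores)
  z <- final_scores - smax
  lse <- log(sum(exp(z)))
  loss <- lse - z[true_index]
  p <- exp(z - lse)
  d <- p
  d[true_index] <- d[true_index] - 1
  attr(loss, "dscores") <- d
  loss
}

# Disjoint union of pre-featurized candidate graphs so one embedding call
# covers every candidate (message passing never crosses fragments).
batch_featurized <- function(graphs) {
  ns <- vapply(graphs, n_atoms, integer(1))
  off <- cumsum(c(0L, ns[-length(ns)]))
  bonds <- do.call(rbind, lapply(seq_along(graphs), function(ci) {
    b <- graphs[[ci]]$bonds
    if (nrow(b) > 0L) { b$i <- b$i + off[ci]; b$j <- b$j + off[ci] }
    b
  }))
  list(elem = unlist(lapply(graphs, `[[`, "elem")),
       bonds = bonds,
       X = do.call(rbind, lapply(graphs, `[[`, "X")),
       E = do.call(rbind, lapply(graphs, `[[`, "E")),
       group = rep(seq_along(graphs), ns))
}

# Score all candidates of one record; returns scores and caches for
# backprop. Candidates share the reactants' atom indexing, so all candidate
# graphs are embedded in one batched call.
wldn_forward_record <- function(rgraph, cand_graphs, prelims, params, config) {
  localR <- wln_embed(rgraph, params, config$depth)
  nR <- nrow(localR)
  ncand <- length(cand_graphs)
  bg <- batch_featurized(cand_graphs)
  localC <- wln_embed(bg, params, config$depth)
  diff <- localC - localR[rep(seq_len(nR), ncand), , drop = FALSE]
  pooled <- rowsum(diff, group = bg$group)        # ncand x h
  pre <- pooled %*% params$Wd
  reps <- relu(pre)
  scores <- as.vector(reps %*% params$wf) + params$bf + prelims
  list(scores = scores, localR = localR, localC = localC, bg = bg,
       pooled = pooled, pre = pre, reps = reps, nR = nR, ncand = ncand)
}

wldn_record_grad <- function(rgraph, cand_graphs, prelims, true_index, params, config) {
  fw <- wldn_forward_record(rgraph, cand_graphs, prelims, params, config)
  loss <- ranking_loss(fw$scores, true_index)
  ds <- attr(loss, "dscores")
  g <- list(wf = as.vector(t(fw$reps) %*% ds), bf = sum(ds))
  dpre <- (ds %o% params$wf) * (fw$pre > 0)       # ncand x h
  g$Wd <- t(fw$pooled) %*% dpre
  dpooled <- dpre %*% t(params$Wd)
  dlocalC <- dpooled[fw$bg$group, , drop = FALSE]
  eg <- wln_embed_backward(dlocalC, attr(fw$localC, "cache"), params)
  dlocalR <- matrix(-colSums(dpooled), fw$nR, config$hidden_dim, byrow = TRUE)
  egR <- wln_embed_backward(dlocalR, attr(fw$localR, "cache"), params)
  list(loss = as.numeric(loss), grads = c(accumulate_grads(eg, egR), g))
}

# Enumerate candidates for ranker training/prediction with a frozen
# reactivity model.
stage1_candidates <- function(record, reactivity_model, K, max_edits) {
  sr <- score_record(reactivity_model, record)
  ch <- top_k_changes(sr$logits, sr$graph, K)
  list(cands = enumerate_candidates(record, ch, max_edits), scored = sr)
}

#' Train the candidate ranker on a frozen reactivity model
#'
#' Candidates are generated per record by the (frozen) stage-1 model;
#' records whose recorded product is absent from the candidate set are
#' skipped and counted. Softmax cross-entropy over candidate scores is
#' minimized with minibatch Adam.
#'
#' @param records Training records.
#' @param reactivity_model A trained `reactivity_model`.
#' @param config A [wldn_config()].
#' @param K,max_edits Enumeration parameters (default: the reactivity
#'   model's config).
#' @return A `ranker_model`: parameters, config, history, and the count of
#'   skipped records.
#' @export
train_ranker <- function(records, reactivity_model, config = wldn_config(),
                         K = NULL, max_edits = NULL) {
  K <- K %||% reactivity_model$config$K
  max_edits <- max_edits %||% reactivity_model$config$max_edits
  set.seed(config$seed)
  sc <- feature_schema()
  params <- wldn_init(config, sc$atom_width, sc$bond_width)
  if (config$share_embedder) {
    for (nm in names(wln_init(config, sc$atom_width, sc$bond_width, scoring = FALSE)))
      params[[nm]] <- reactivity_model$params[[nm]]
  }
  # fixed training instances from the frozen stage-1 model
  inst <- list(); n_skipped <- 0L
  for (rec in records) {
    if (rec$no_reaction || rec$too_many_edits) { n_skipped <- n_skipped + 1L; next }
    s1 <- stage1_candidates(rec, reactivity_model, K, max_edits)
    cands <- s1$cands
    if (length(cands) == 0L) { n_skipped <- n_skipped + 1L; next }
    truth <- rec$product_smiles
    ti <- which(vapply(cands, function(cc) exact_match(cc$product_smiles, truth),
                       logical(1)))
    if (length(ti) == 0L) { n_skipped <- n_skipped + 1L; next }
    ti <- ti[1]
    keep <- seq_along(cands)
    if (is.finite(config$max_train_candidates) &&
        length(cands) > config$max_train_candidates) {
      keep <- union(ti, seq_len(config$max_train_candidates))
      keep <- keep[seq_len(config$max_train_candidates)]
      if (!(ti %in% keep)) keep[length(keep)] <- ti
    }
    cands <- cands[keep]
    ti <- match(ti, keep)
    rgraph <- featurize_plain(rec$reactants)
    cgraphs <- lapply(cands, function(cc) featurize_plain(cc$graph))
    prelims <- vapply(cands, `[[`, numeric(1), "preliminary_score")
    inst[[length(inst) + 1L]] <- list(rgraph = rgraph, cgraphs = cgraphs,
                                      prelims = prelims, true_index = ti)
  }
  if (length(inst) == 0L) stop("no trainable records for the ranker")
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    idx <- sample(length(inst))
    total <- 0
    for (start in seq(1L, length(idx), by = config$batch_size)) {
      batch <- idx[start:min(start + config$batch_size - 1L, length(idx))]
      acc <- NULL
      for (b in batch) {
        ii <- inst[[b]]
        rg <- wldn_record_grad(ii$rgraph, ii$cgraphs, ii$prelims, ii$true_index,
                               params, config)
        if (!is.finite(rg$loss))
          stop(errorCondition(sprintf("ranker training diverged at epoch %d", ep),
                              class = c("rxn_numeric_error", "error")))
        total <- total + rg$loss
        acc <- accumulate_grads(acc, rg$grads)
      }
      acc <- lapply(acc, function(x) x / length(batch))
      st <- adam_step(params, acc, state, config$lr)
      params <- st$params; state <- st$state
    }
    history <- rbind(history, data.frame(epoch = ep, loss = total / length(inst)))
  }
  structure(list(params = params, config = config, history = history,
                 n_skipped = n_skipped), class = "ranker_model")
}

#' Bundle the two trained stages into a prediction pipeline
#'
#' @param reactivity A `reactivity_model`.
#' @param ranker A `ranker_model` (optional; without it, candidates are
#'   ranked by preliminary score alone).
#' @return An `rxn_pipeline` object with a [predict()][predict.rxn_pipeline]
#'   method.
#' @export
rxn_pipeline <- function(reactivity, ranker = NULL) {
  structure(list(reactivity = reactivity, ranker = ranker),
            class = "rxn_pipeline")
}

# Build a minimal record from unmapped (or mapped) reactant input at
# predict time: maps are assigned 1..n when absent; a ">"-free string is
# all reactants, "reactants>reagents" supplies a reagent field.
as_predict_record <- function(input) {
  if (inherits(input, "reaction_record")) return(input)
  parts <- strsplit(input, ">", fixed = TRUE)[[1]]
  reactants_smiles <- parts[1]
  reagents_smiles <- if (length(parts) >= 2L) parts[2] else ""
  g <- smiles_to_graph(reactants_smiles)
  if (all(g$map == 0L)) {
    g$map <- seq_len(n_atoms(g))
    reactants_smiles <- graph_to_smiles(g, include_maps = TRUE)
  } else if (any(g$map == 0L) || anyDuplicated(g$map[g$map > 0L])) {
    mapping_error("reactant input must be fully atom-mapped or fully unmapped")
  }
  rec <- list(reactants_smiles = reactants_smiles,
              reagents_smiles = reagents_smiles,
              product_smiles = "", reactants = g, product = NULL,
              edits = bond_changes(), reactive_mask = rep(TRUE, max(g$species)),
              no_reaction = FALSE, too_many_edits = FALSE, meta = list())
  class(rec) <- "reaction_record"
  rec
}

#' Predict ranked reaction outcomes
#'
#' Runs the full pipeline on one input: featurize, score bond changes,
#' take the top-K, enumerate candidates, rank with the difference network,
#' and return a probability distribution over predicted products.
#'
#' @param object An `rxn_pipeline`.
#' @param newdata A `reaction_record`, or a reactant SMILES string
#'   (optionally `"reactants>reagents"`); unmapped input is mapped
#'   internally.
#' @param K,max_edits Override the enumeration parameters.
#' @param top_n Truncate the returned candidate list.
#' @param ... Unused.
#' @return A `ranked_prediction`: data.frame `candidates` (rank,
#'   product_smiles, probability, final_score, preliminary_score, edits as
#'   a list column), `attention` matrix, and `no_prediction` flag when the
#'   candidate set is empty.
#' @export
predict.rxn_pipeline <- function(object, newdata, K = NULL, max_edits = NULL,
                                 top_n = Inf, ...) {
  record <- as_predict_record(newdata)
  K <- K %||% object$reactivity$config$K
  max_edits <- max_edits %||% object$reactivity$config$max_edits
  s1 <- stage1_candidates(record, object$reactivity, K, max_edits)
  cands <- s1$cands
  if (length(cands) == 0L) {
    return(structure(list(candidates = data.frame(), attention = s1$scored$attention,
                          no_prediction = TRUE), class = "ranked_prediction"))
  }
  prelims <- vapply(cands, `[[`, numeric(1), "preliminary_score")
  if (!is.null(object$ranker)) {
    rcfg <- object$ranker$config
    rgraph <- featurize_plain(record$reactants)
    cgraphs <- lapply(cands, function(cc) featurize_plain(cc$graph))
    fw <- wldn_forward_record(rgraph, cgraphs, prelims, object$ranker$params, rcfg)
    finals <- fw$scores
  } else {
    finals <- prelims
  }
  smis <- vapply(cands, `[[`, character(1), "product_smiles")
  ordn <- order(-finals, -prelims, smis, method = "radix")
  finals <- finals[ordn]; prelims <- prelims[ordn]; smis <- smis[ordn]
  cands <- cands[ordn]
  z <- finals - max(finals)
  probs <- exp(z) / sum(exp(z))
  n_keep <- min(length(cands), top_n)
  out <- data.frame(rank = seq_len(n_keep),
                    product_smiles = smis[seq_len(n_keep)],
                    probability = probs[seq_len(n_keep)],
                    final_score = finals[seq_len(n_keep)],
                    preliminary_score = prelims[seq_len(n_keep)])
  out$edits <- lapply(cands[seq_len(n_keep)], `[[`, "edit_combo")
  structure(list(candidates = out, attention = s1$scored$attention,
                 no_prediction = FALSE), class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  if (x$no_prediction) {
    cat("<ranked_prediction: no candidates>\n")
  } else {
    cat(sprintf("<ranked_prediction: %d candidates>\n", nrow(x$candidates)))
    print(utils::head(x$candidates[, c("rank", "product_smiles", "probability")], 5))
  }
  invisible(x)
}

#' Top-k exact-match accuracy
#'
#' @param predictions List of `ranked_prediction`, aligned with `records`.
#' @param records Reference records with recorded products.
#' @param ks Integer vector of k values.
#' @return `data.frame` with columns `k`, `accuracy`, `n`.
#' @export
topk_accuracy <- function(predictions, records, ks = c(1L, 2L, 3L, 5L)) {
  if (length(predictions) != length(records))
    stop(errorCondition("predictions and records differ in length",
                        class = c("rxn_data_error", "error")))
  match_rank <- vapply(seq_along(records), function(ii) {
    pred <- predictions[[ii]]
    if (pred$no_prediction || nrow(pred$candidates) == 0L) return(Inf)
    truth <- records[[ii]]$product_smiles
    hits <- which(vapply(pred$candidates$product_smiles, function(s)
      exact_match(s, truth), logical(1)))
    if (length(hits) == 0L) Inf else min(pred$candidates$rank[hits])
  }, numeric(1))
  data.frame(k = sort(ks),
             accuracy = vapply(sort(ks), function(k) mean(match_rank <= k), numeric(1)),
             n = length(records))
}
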