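# Weisfeiler-Lehman network over reactant graphs: iterative neighborhood
# embedding, a local feature per atom, a global attention context so every
# atom can see disconnected species (reagents), and per-atom-pair
# per-bond-order change logits. Forward and reverse passes are explicit
# matrix code; gradients are validated against finite differences in the
# test suite.

#' WLN configuration
#'
#' @param hidden_dim Width of atom representations.
#' @param depth Number of message-passing iterations (>= 1).
#' @param K Number of top bond changes fed to the enumerator.
#' @param max_edits Maximum number of bond changes per candidate (<= 5).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (records per gradient step).
#' @param self_attention Include each atom in its own attention row.
#' @param att_entropy Weight of the attention entropy regularizer. The
#'   sigmoid-normalized attention can saturate onto a few atoms early in
#'   training, silencing the gradient path from disconnected reagents; a
#'   small penalty on negative row entropy keeps every path alive. 0
#'   disables it.
#' @param seed RNG seed for parameter initialization and shuffling.
#' @return A `wln_config` list.
#' @export
wln_config <- function(hidden_dim = 300L, depth = 3L, K = 20L, max_edits = 5L,
                       lr = 1e-3, epochs = 10L, batch_size = 16L,
                       self_attention = TRUE, att_entropy = 0.1, seed = 1L) {
  stopifnot(hidden_dim >= 1L)
  if (depth < 1L)
    stop(errorCondition("depth must be >= 1", class = c("rxn_config_error", "error")))
  if (max_edits < 1L || max_edits > 5L)
    stop(errorCondition("max_edits must be in 1..5", class = c("rxn_config_error", "error")))
  structure(list(hidden_dim = as.integer(hidden_dim), depth = as.integer(depth),
                 K = as.integer(K), max_edits = as.integer(max_edits), lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 self_attention = isTRUE(self_attention),
                 att_entropy = att_entropy, seed = as.integer(seed)),
            class = "wln_config")
}

N_ORDER_CHANNELS <- 5L  # one output head per bond order in {0, 1, 1.5, 2, 3}

rand_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

# Parameter set for the scoring WLN. `scoring = FALSE` builds only the
# embedding trunk (used by the difference-network ranker).
wln_init <- function(config, atom_dim, bond_dim, scoring = TRUE) {
  h <- config$hidden_dim
  p <- list(
    W0 = rand_mat(atom_dim, h), b0 = numeric(h),
    U1 = rand_mat(h, h), U2 = rand_mat(bond_dim, h), bu = numeric(h),
    W1 = rand_mat(h, h), W2 = rand_mat(h, h), bw = numeric(h),
    V1 = rand_mat(h, h), V2 = rand_mat(h, h), bv = numeric(h)
  )
  if (scoring) {
    p <- c(p, list(
      # the attention head starts near zero score everywhere: a saturated
      # sigmoid at initialization can freeze attention onto an arbitrary
      # atom subset (excluding e.g. reagents) before training can use it
      Wa1 = rand_mat(h, h), Wa2 = rand_mat(h, h),
      wa = stats::runif(h, -1, 1) / (10 * h),
      Wp = rand_mat(h, h), bp = numeric(h),
      Wo = rand_mat(h, N_ORDER_CHANNELS), bo = numeric(N_ORDER_CHANNELS)
    ))
  }
  p
}

relu <- function(x) x * (x > 0)

# Directed edge list (src, tgt, bond row) for message passing.
directed_edges <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(list(src = integer(0), tgt = integer(0), brow = integer(0)))
  list(src = c(g$bonds$i, g$bonds$j),
       tgt = c(g$bonds$j, g$bonds$i),
       brow = c(seq_len(nb), seq_len(nb)))
}

adj_matrix <- function(g) {
  n <- n_atoms(g)
  A <- matrix(0, n, n)
  if (nrow(g$bonds) > 0L) {
    A[cbind(g$bonds$i, g$bonds$j)] <- 1
    A[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  A
}

group_rowsum <- function(m, group, n) {
  out <- matrix(0, n, ncol(m))
  if (nrow(m) > 0L) {
    rs <- rowsum(m, group = group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

#' Embed atoms with iterative Weisfeiler-Lehman message passing
#'
#' Each of `depth` iterations updates every atom's state from its own state
#' and a sum of learned messages over adjacent (atom, bond) pairs; the final
#' local feature combines each atom's state with its aggregated neighbors.
#' An isolated atom receives no messages, so its embedding depends on its
#' own features only.
#'
#' @param graph A featurized `mol_graph` (see [build_reactant_graph()]).
#' @param params Parameter list from the trained model.
#' @param depth Number of iterations (>= 1).
#' @return Matrix of per-atom local vectors with the forward cache attached
#'   as attribute `"cache"`.
#' @export
wln_embed <- function(graph, params, depth) {
  if (depth < 1L)
    stop(errorCondition("depth must be >= 1", class = c("rxn_config_error", "error")))
  n <- n_atoms(graph)
  de <- directed_edges(graph)
  Eedge <- graph$E[de$brow, , drop = FALSE]
  Hsrc_pre <- graph$X %*% params$W0
  H0pre <- sweep(Hsrc_pre, 2, params$b0, "+")
  H <- relu(H0pre)
  iters <- vector("list", depth)
  for (t in seq_len(depth)) {
    msg_pre <- matrix(0, length(de$src), ncol(H))
    if (length(de$src) > 0L) {
      msg_pre <- H[de$src, , drop = FALSE] %*% params$U1 + Eedge %*% params$U2
      msg_pre <- sweep(msg_pre, 2, params$bu, "+")
    }
    msg <- relu(msg_pre)
    M <- group_rowsum(msg, de$tgt, n)
    Hpre <- sweep(H %*% params$W1 + M %*% params$W2, 2, params$bw, "+")
    Hout <- relu(Hpre)
    if (!all(is.finite(Hout)))
      stop(errorCondition(sprintf("non-finite activations at embedding iteration %d", t),
                          class = c("rxn_numeric_error", "error")))
    iters[[t]] <- list(Hin = H, msg_pre = msg_pre, M = M, Hpre = Hpre)
    H <- Hout
  }
  A <- adj_matrix(graph)
  AH <- A %*% H
  Lpre <- sweep(H %*% params$V1 + AH %*% params$V2, 2, params$bv, "+")
  local <- relu(Lpre)
  attr(local, "cache") <- list(H0pre = H0pre, iters = iters, Hfinal = H,
                               A = A, AH = AH, Lpre = Lpre, de = de,
                               Eedge = Eedge, X = graph$X)
  local
}

# Reverse pass of wln_embed. `dlocal` is the gradient at the local vectors;
# returns parameter gradients (accumulated over shared iterations).
wln_embed_backward <- function(dlocal, cache, params) {
  g <- list()
  dLpre <- dlocal * (cache$Lpre > 0)
  g$V1 <- t(cache$Hfinal) %*% dLpre
  g$V2 <- t(cache$AH) %*% dLpre
  g$bv <- colSums(dLpre)
  dH <- dLpre %*% t(params$V1) + cache$A %*% (dLpre %*% t(params$V2))
  de <- cache$de
  h <- ncol(dH)
  g$U1 <- matrix(0, h, h); g$U2 <- matrix(0, ncol(cache$Eedge), h); g$bu <- numeric(h)
  g$W1 <- matrix(0, h, h); g$W2 <- matrix(0, h, h); g$bw <- numeric(h)
  for (t in rev(seq_along(cache$iters))) {
    it <- cache$iters[[t]]
    dHpre <- dH * (it$Hpre > 0)
    g$W1 <- g$W1 + t(it$Hin) %*% dHpre
    g$W2 <- g$W2 + t(it$M) %*% dHpre
    g$bw <- g$bw + colSums(dHpre)
    dHin <- dHpre %*% t(params$W1)
    dM <- dHpre %*% t(params$W2)
    if (length(de$src) > 0L) {
      dmsg <- dM[de$tgt, , drop = FALSE]
      dmsg_pre <- dmsg * (it$msg_pre > 0)
      g$U1 <- g$U1 + t(it$Hin[de$src, , drop = FALSE]) %*% dmsg_pre
      g$U2 <- g$U2 + t(cache$Eedge) %*% dmsg_pre
      g$bu <- g$bu + colSums(dmsg_pre)
      dHin <- dHin + group_rowsum(dmsg_pre %*% t(params$U1), de$src, nrow(dH))
    }
    dH <- dHin
  }
  dH0pre <- dH * (cache$H0pre > 0)
  g$W0 <- t(cache$X) %*% dH0pre
  g$b0 <- colSums(dH0pre)
  g
}

#' Global attention over all atoms
#'
#' Every atom attends to every atom in the reactant graph, including
#' disconnected species; attention strength is an additive score passed
#' through a sigmoid, normalized per row. The context vector of atom u is
#' the attention-weighted sum of all local vectors.
#'
#' @param local Per-atom local vectors from [wln_embed()].
#' @param params Parameter list.
#' @param self_attention Include the diagonal; when `FALSE` each atom
#'   attends only to the other atoms (a single-atom graph then keeps weight
#'   1 on itself to stay normalizable).
#' @return List with `context` (matrix), `attention` (row-normalized n x n
#'   weights) and the forward cache.
#' @export
global_attention <- function(local, params, self_attention = TRUE) {
  n <- nrow(local)
  P1 <- local %*% params$Wa1
  P2 <- local %*% params$Wa2
  iu <- rep(seq_len(n), each = n)
  iv <- rep(seq_len(n), times = n)
  Rpre <- P1[iu, , drop = FALSE] + P2[iv, , drop = FALSE]
  R <- relu(Rpre)
  S <- matrix(R %*% params$wa, n, n, byrow = TRUE)  # S[u, v]
  sig <- 1 / (1 + exp(-S))
  if (!self_attention && n > 1L) diag(sig) <- 0
  rs <- rowSums(sig)
  att <- sig / rs
  context <- att %*% local
  list(context = context, attention = att,
       cache = list(local = local, P1 = P1, P2 = P2, Rpre = Rpre, R = R,
                    sig = sig, rs = rs, att = att, iu = iu, iv = iv,
                    self_attention = self_attention))
}

# Reverse pass of global_attention; returns parameter grads and dlocal.
global_attention_backward <- function(dcontext, datt_extra, cache, params) {
  n <- nrow(cache$local)
  att <- cache$att
  dlocal <- t(att) %*% dcontext
  datt <- dcontext %*% t(cache$local)
  if (!is.null(datt_extra)) datt <- datt + datt_extra
  # att = sig / rowSums(sig)
  dsig <- sweep(datt, 1, rowSums(datt * att), "-") / cache$rs
  if (!cache$self_attention && n > 1L) diag(dsig) <- 0
  dS <- dsig * cache$sig * (1 - cache$sig)
  dRw <- as.vector(t(dS))  # matches R's row-major (u,v) flattening
  dR <- outer(dRw, params$wa)
  dwa <- as.vector(t(cache$R) %*% dRw)
  dRpre <- dR * (cache$Rpre > 0)
  dP1 <- group_rowsum(dRpre, cache$iu, n)
  dP2 <- group_rowsum(dRpre, cache$iv, n)
  g <- list(Wa1 = t(cache$local) %*% dP1, Wa2 = t(cache$local) %*% dP2, wa = dwa)
  dlocal <- dlocal + dP1 %*% t(params$Wa1) + dP2 %*% t(params$Wa2)
  list(grads = g, dlocal = dlocal)
}

#' Score bond changes for every atom pair and bond order
#'
#' The pairwise sum of each atom's (local + context) representation feeds a
#' shared hidden layer and one output head per bond order in
#' {0, 1, 1.5, 2, 3}. The sum makes the logits exactly symmetric in (i, j).
#'
#' @param local,context Matrices from [wln_embed()] / [global_attention()].
#' @param params Parameter list.
#' @return List with `logits` (n x n x 5 array, channel order 0/1/1.5/2/3)
#'   and the forward cache; `likelihood = sigmoid(logit)`.
#' @export
score_bond_changes <- function(local, context, params) {
  n <- nrow(local)
  pav <- local + context
  iu <- rep(seq_len(n), each = n)
  iv <- rep(seq_len(n), times = n)
  Tm <- pav[iu, , drop = FALSE] + pav[iv, , drop = FALSE]
  Qpre <- sweep(Tm %*% params$Wp, 2, params$bp, "+")
  Q <- relu(Qpre)
  Lg <- sweep(Q %*% params$Wo, 2, params$bo, "+")  # n^2 x 5
  logits <- array(0, c(n, n, N_ORDER_CHANNELS))
  for (o in seq_len(N_ORDER_CHANNELS)) logits[, , o] <- matrix(Lg[, o], n, n, byrow = TRUE)
  list(logits = logits,
       cache = list(pav = pav, Tm = Tm, Qpre = Qpre, Q = Q, iu = iu, iv = iv, n = n))
}

# Reverse pass of score_bond_changes. `dlogits` is n x n x 5; returns grads
# and the gradient w.r.t. pav (= dlocal and dcontext, which are equal).
score_bond_changes_backward <- function(dlogits, cache, params) {
  n <- cache$n
  dLg <- matrix(0, n * n, N_ORDER_CHANNELS)
  for (o in seq_len(N_ORDER_CHANNELS)) dLg[, o] <- as.vector(t(dlogits[, , o]))
  g <- list(Wo = t(cache$Q) %*% dLg, bo = colSums(dLg))
  dQ <- dLg %*% t(params$Wo)
  dQpre <- dQ * (cache$Qpre > 0)
  g$Wp <- t(cache$Tm) %*% dQpre
  g$bp <- colSums(dQpre)
  dT <- dQpre %*% t(params$Wp)
  dpav <- group_rowsum(dT, cache$iu, n) + group_rowsum(dT, cache$iv, n)
  list(grads = g, dpav = dpav)
}

# Full forward pass on one featurized reactant graph.
wln_forward <- function(graph, params, config) {
  local <- wln_embed(graph, params, config$depth)
  at <- global_attention(local, params, config$self_attention)
  sc <- score_bond_changes(local, at$context, params)
  list(local = local, context = at$context, attention = at$attention,
       logits = sc$logits, caches = list(embed = attr(local, "cache"),
                                         att = at$cache, score = sc$cache))
}

# Label array and slot mask for one record on its featurized graph.
# Slots are (u < v, order channel) with both atoms reactive.
reactivity_targets <- function(graph, edits) {
  n <- n_atoms(graph)
  labels <- array(0, c(n, n, N_ORDER_CHANNELS))
  mask <- array(FALSE, c(n, n, N_ORDER_CHANNELS))
  reactive <- graph$reactive
  if (is.null(reactive)) reactive <- rep(TRUE, n)
  m2 <- outer(reactive, reactive, "&") & upper.tri(matrix(TRUE, n, n))
  mask <- array(rep(m2, N_ORDER_CHANNELS), c(n, n, N_ORDER_CHANNELS))
  if (nrow(edits) > 0L) {
    ai <- match(edits$i, graph$map)
    aj <- match(edits$j, graph$map)
    if (anyNA(ai) || anyNA(aj))
      mapping_error("true edit references an unmapped atom")
    for (k in seq_len(nrow(edits))) {
      u <- min(ai[k], aj[k]); v <- max(ai[k], aj[k])
      o <- match(edits$order[k], BOND_ORDERS)
      if (!mask[u, v, o])
        stop(errorCondition("true edit lies on a masked (non-reactant) pair",
                            class = c("rxn_data_error", "error")))
      labels[u, v, o] <- 1
    }
  }
  list(labels = labels, mask = mask)
}

#' Sigmoid cross-entropy loss over bond-change slots
#'
#' Sums, over every unordered reactive atom pair and every bond-order
#' channel, the binary cross-entropy between the predicted change
#' likelihood `sigmoid(logit)` and membership of the slot in the true edit
#' set. Pairs touching non-reactive species are masked out.
#'
#' @param logits n x n x 5 array from [score_bond_changes()].
#' @param labels,mask Arrays from the record's targets.
#' @return Scalar loss; attribute `"dlogits"` holds its gradient.
#' @export
reactivity_loss <- function(logits, labels, mask) {
  z <- logits[mask]
  y <- labels[mask]
  # numerically stable BCE-with-logits: max(z,0) - z*y + log(1+exp(-|z|))
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dl <- array(0, dim(logits))
  dl[mask] <- 1 / (1 + exp(-z)) - y
  attr(loss, "dlogits") <- dl
  loss
}

# Loss and parameter gradients for one record; the attention entropy
# penalty (config$att_entropy * sum(a log a)) is added to the objective.
reactivity_record_grad <- function(graph, edits, params, config, targets = NULL) {
  fw <- wln_forward(graph, params, config)
  tg <- if (is.null(targets)) reactivity_targets(graph, edits) else targets
  loss <- reactivity_loss(fw$logits, tg$labels, tg$mask)
  total <- as.numeric(loss)
  datt_extra <- NULL
  lam <- config$att_entropy %||% 0
  if (lam > 0) {
    a <- pmax(fw$attention, 1e-12)
    total <- total + lam * sum(a * log(a))
    datt_extra <- lam * (log(a) + 1)
  }
  sb <- score_bond_changes_backward(attr(loss, "dlogits"), fw$caches$score, params)
  ab <- global_attention_backward(sb$dpav, datt_extra, fw$caches$att, params)
  dlocal <- sb$dpav + ab$dlocal
  eb <- wln_embed_backward(dlocal, fw$caches$embed, params)
  grads <- c(eb, ab$grads, sb$grads)
  list(loss = total, grads = grads)
}

#' Select the K most likely bond changes
#'
#' Ranks all (atom pair, new order) triples by predicted likelihood,
#' excluding self pairs, triples whose order equals the pair's current
#' order, and triples touching non-reactive species. Ties break by
#' (likelihood desc, i asc, j asc, order asc) over atom-map ids.
#'
#' @param logits n x n x 5 logit array.
#' @param graph The featurized reactant graph the logits were computed on.
#' @param K Number of changes to return (>= 1).
#' @return `data.frame` with map-id columns `i`, `j`, `order`, `likelihood`,
#'   at most K rows, ordered.
#' @export
top_k_changes <- function(logits, graph, K) {
  if (K < 1L)
    stop(errorCondition("K must be >= 1", class = c("rxn_config_error", "error")))
  n <- n_atoms(graph)
  reactive <- graph$reactive
  if (is.null(reactive)) reactive <- rep(TRUE, n)
  empty <- data.frame(i = integer(0), j = integer(0),
                      order = numeric(0), likelihood = numeric(0))
  if (n < 2L) return(empty)
  pair_ok <- outer(reactive, reactive, "&") & upper.tri(matrix(TRUE, n, n))
  pr <- which(pair_ok, arr.ind = TRUE)
  if (nrow(pr) == 0L) return(empty)
  cur <- matrix(0, n, n)
  if (nrow(graph$bonds) > 0L) {
    cur[cbind(graph$bonds$i, graph$bonds$j)] <- graph$bonds$order
    cur[cbind(graph$bonds$j, graph$bonds$i)] <- graph$bonds$order
  }
  u <- rep(pr[, 1], N_ORDER_CHANNELS)
  v <- rep(pr[, 2], N_ORDER_CHANNELS)
  oo <- rep(BOND_ORDERS, each = nrow(pr))
  keep <- oo != cur[cbind(u, v)]
  u <- u[keep]; v <- v[keep]; oo <- oo[keep]
  lg <- logits[cbind(u, v, match(oo, BOND_ORDERS))]
  mi <- pmin(graph$map[u], graph$map[v])
  mj <- pmax(graph$map[u], graph$map[v])
  lik <- 1 / (1 + exp(-lg))
  ord <- order(-lik, mi, mj, oo)
  ord <- ord[seq_len(min(K, length(ord)))]
  data.frame(i = as.integer(mi[ord]), j = as.integer(mj[ord]),
             order = oo[ord], likelihood = lik[ord])
}

# ---------------------------------------------------------------------------
# Adam optimizer over a named list of parameter arrays

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    ggrad <- grads[[nm]]
    if (is.null(ggrad)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * ggrad
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * ggrad^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

#' Train the bond-change scoring WLN
#'
#' Minibatch Adam on the summed sigmoid cross-entropy over training
#' records. Records flagged no-reaction or with more than 5 edits are
#' excluded with a warning. History tracks per-epoch mean loss and, when a
#' validation set is given, edit-recall@K (fraction of records whose full
#' true edit set is contained in the top-K changes).
#'
#' @param records List of `reaction_record` (training set).
#' @param config A [wln_config()].
#' @param valid Optional validation records.
#' @return A `reactivity_model`: parameters, config, training history.
#' @export
train_reactivity <- function(records, config = wln_config(), valid = NULL) {
  drop <- vapply(records, function(r) r$no_reaction || r$too_many_edits, logical(1))
  if (any(drop))
    warning(sprintf("excluding %d record(s) with 0 or >5 edits from training", sum(drop)))
  records <- records[!drop]
  if (length(records) == 0L) stop("no trainable records")
  set.seed(config$seed)
  sc <- feature_schema()
  params <- wln_init(config, sc$atom_width, sc$bond_width, scoring = TRUE)
  graphs <- lapply(records, build_reactant_graph)
  targets <- lapply(seq_along(records), function(ii)
    reactivity_targets(graphs[[ii]], records[[ii]]$edits))
  vgraphs <- if (!is.null(valid)) lapply(valid, build_reactant_graph) else NULL
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0), recall_at_K = numeric(0))
  for (ep in seq_len(config$epochs)) {
    idx <- sample(length(records))
    total <- 0
    for (start in seq(1L, length(idx), by = config$batch_size)) {
      batch <- idx[start:min(start + config$batch_size - 1L, length(idx))]
      acc <- NULL
      for (b in batch) {
        rg <- reactivity_record_grad(graphs[[b]], records[[b]]$edits, params, config,
                                     targets = targets[[b]])
        if (!is.finite(rg$loss))
          stop(errorCondition(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                              class = c("rxn_numeric_error", "error")))
        total <- total + rg$loss
        acc <- accumulate_grads(acc, rg$grads)
      }
      acc <- lapply(acc, function(x) x / length(batch))
      st <- adam_step(params, acc, state, config$lr)
      params <- st$params; state <- st$state
    }
    rec_k <- NA_real_
    if (!is.null(valid)) {
      model_now <- structure(list(params = params, config = config), class = "reactivity_model")
      rec_k <- edit_recall_at_k(model_now, valid, config$K, graphs = vgraphs)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = total / length(records),
                                         recall_at_K = rec_k))
  }
  structure(list(params = params, config = config, history = history),
            class = "reactivity_model")
}

#' Predict bond-change scores for one record
#'
#' @param model A trained `reactivity_model`.
#' @param record A `reaction_record` (or anything [build_reactant_graph()] accepts).
#' @param graph Optional pre-built featurized graph.
#' @return List with the featurized `graph`, `logits`, `attention`, `local`,
#'   `context`.
#' @export
score_record <- function(model, record, graph = NULL) {
  if (is.null(graph)) graph <- build_reactant_graph(record)
  fw <- wln_forward(graph, model$params, model$config)
  list(graph = graph, logits = fw$logits, attention = fw$attention,
       local = fw$local, context = fw$context)
}

#' Edit recall at K over a record set
#'
#' Fraction of records whose entire true edit set appears among the top-K
#' predicted bond changes.
#'
#' @param model A `reactivity_model`.
#' @param records Evaluation records.
#' @param K Number of candidate changes considered.
#' @param graphs Optional pre-built featurized graphs.
#' @return Fraction in `[0, 1]`.
#' @export
edit_recall_at_k <- function(model, records, K, graphs = NULL) {
  hit <- vapply(seq_along(records), function(ii) {
    g <- if (!is.null(graphs)) graphs[[ii]] else build_reactant_graph(records[[ii]])
    fw <- wln_forward(g, model$params, model$config)
    top <- top_k_changes(fw$logits, g, K)
    all(edit_key(records[[ii]]$edits) %in% edit_key(top))
  }, logical(1))
  mean(hit)
}
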