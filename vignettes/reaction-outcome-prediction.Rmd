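---
title: "Predicting reaction outcomes as ranked graph edits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reaction outcomes as ranked graph edits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnwln)
```

## The prediction task

Given a pool of reactant and reagent molecules, which product does the
reaction actually form? `rxnwln` frames this as predicting **graph edits**:
a reaction is a small set of (atom, atom, new bond order) changes imposed on
the reactant graph, with order 0 meaning a bond is removed and order 1.5 an
aromatic bond. Almost all recorded organic reactions change at most five
bonds, so the package treats 5 as a hard cap: records with larger edit sets
are excluded from training with a warning, and candidate generation never
combines more than five changes.

The pipeline has two learned stages wrapped around a combinatorial core:

1. **Reactivity perception.** A Weisfeiler-Lehman network (WLN) over the
   merged reactant graph scores, for every atom pair and every bond order in
   {0, 1, 1.5, 2, 3}, the likelihood that the pair changes to that order.
2. **Focused enumeration.** The top-*K* changes are combined (1 to
   `max_edits` changes per combination, pairwise-distinct atom pairs) and
   applied to the reactants. The number of generated subsets is bounded by
   `sum(choose(K, 1:max_edits))`. Valence and connectivity filters prune
   the chemically impossible, and survivors are deduplicated by canonical
   SMILES.
3. **Ranking.** A Weisfeiler-Lehman difference network (WLDN) embeds each
   candidate and the reactants with a shared trunk, pools the per-atom
   representation differences, and scores each candidate as a linear head
   on that reaction representation **plus** the candidate's preliminary
   score (the sum of its constituent change likelihoods). A softmax over
   final scores is the predicted probability distribution over products.

## Model details

### Featurization

Atoms carry concatenated one-hots: element (20 common organic and
organometallic elements plus "other"), formal charge clamped to −2..+2,
heavy-atom degree 0..5, explicit valence 0..6 (total explicit bond order,
aromatic orders floored after summation), implicit valence 0..6 (implicit
hydrogen count), and an aromaticity bit — 47 numbers per atom. Bonds carry
a bond-order one-hot over {1, 1.5, 2, 3} and a ring bit — 5 numbers. No
further descriptors are used; the width is asserted in the test suite so
nothing can creep in silently.

### The WLN update

With atom features $x_a$ and bond features $e_{ab}$, the trunk computes
$h_a^{(0)} = \mathrm{ReLU}(W_0 x_a)$ and then, for $t = 1 \dots d$ with
shared weights,

$$
m_a^{(t)} = \sum_{b \in N(a)} \mathrm{ReLU}(U_1 h_b^{(t-1)} + U_2 e_{ab}),
\qquad
h_a^{(t)} = \mathrm{ReLU}(W_1 h_a^{(t-1)} + W_2 m_a^{(t)}).
$$

The local feature combines each atom's final state with its aggregated
neighbors, $\ell_a = \mathrm{ReLU}(V_1 h_a^{(d)} + V_2 \sum_{b\in N(a)}
h_b^{(d)})$. An isolated atom receives no messages, so its embedding is a
function of its own features only.

### Global attention

Disconnected species — bases, catalysts, activating reagents — can decide
the outcome without sharing a bond with the substrate. Every atom therefore
attends to every atom: the attention strength is an additive score
$s_{uv} = w^\top \mathrm{ReLU}(A_1 \ell_u + A_2 \ell_v)$ passed through a
sigmoid and normalized per row, and the context vector is
$c_u = \sum_v a_{uv} \ell_v$. Self-attention is included by default (a flag
exposes the exclusive variant; with a single atom the inclusive form is the
only normalizable one). Attention rows are exported per reaction for
interpretation: a large weight from a reacting atom onto a reagent means
the reagent shaped that atom's perceived reactivity.

Two empirical observations at desk scale shaped the defaults. First, the
sigmoid-normalized attention can *collapse early*: on some seeds the
scores saturate onto a few substrate atoms within the first epochs,
driving the weight on reagent atoms to ~1e-7 with vanishing sigmoid
gradients — after which the model is permanently blind to the reagent and
reagent-conditional outcomes are never learned. A small penalty on
negative attention-row entropy (`att_entropy`, default 0.1, added to the
training objective with its exact gradient) keeps every path alive and
made the conditional family train successfully on every seed tried,
without hurting the unconditional families.

Second, because the local embeddings already encode each atom's full
feature conjunction, the *uniform* attention row — whose context is the
mean of all local vectors — already preserves every linearly detectable
signal, including "a hydroxide is present"; without the regularizer,
runs that did learn the conditioning often did so through an exactly
uniform attention map. With the regularizer keeping the mechanism alive,
the trained attention shows moderate, chemically sensible contrast (the
reacting oxygen of the base-conditional family weights the base roughly
twice its uniform share), while the reagent-withholding flip experiment
remains the sharper conditioning diagnostic at this scale.

### Pair scores and losses

The pair representation is the **sum** $(\ell_u + c_u) + (\ell_v + c_v)$,
which makes the per-order logits exactly symmetric in $(u, v)$ by
construction — the test suite checks identity, not approximation. Training
minimizes the summed sigmoid cross-entropy over all (pair, order) slots
against membership in the recorded edit set. Species that contribute no
heavy atom to the recorded product (reagents, inert co-solvents) are
masked: their pairs contribute no loss and are never selected into the
top-*K*. A recorded edit touching a masked species is a data error, not a
silent drop.

The ranker minimizes softmax cross-entropy over each record's candidate
set; records whose true product did not survive enumeration are skipped
and counted. The ranker is trained on candidates from the *frozen*
stage-1 model (two-stage, not joint), and uses its own trunk parameters —
sharing with the reactivity WLN is exposed as a flag but off by default,
since the two tasks shape representations differently.

Because the preliminary score is a **raw-likelihood sum**, any superset of
a good edit combination scores at least as high as the combination itself;
demoting such parasitic supersets is the ranker's main correction on the
synthetic families. Note that the ranker never sees the reagent field
(reagent atoms are unedited, so they cancel exactly in the difference
representation): on a reagent-conditional task its capacity should be kept
small (`hidden_dim` 8 and a handful of epochs in the shipped experiments),
because a wide ranker can only reduce its loss by memorizing
substrate-outcome pairs from the training split, which destroys held-out
conditioning. A log-domain preliminary score (`log_domain = TRUE` in
`enumerate_candidates()`) penalizes supersets directly and is available as
an alternative.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `hidden_dim` | 300 | atom representation width |
| `depth` | 3 | message-passing iterations (radius of the perceived environment) |
| `K` | 20 | bond changes fed to the enumerator; larger K trades candidates for coverage |
| `max_edits` | 5 | changes per combination; 5 covers essentially all recorded reactions |
| `lr` | 1e-3 | Adam step size |
| `self_attention` | TRUE | include the diagonal in attention rows |
| `att_entropy` | 0.1 | weight of the attention entropy regularizer |
| `max_train_candidates` | 16 | ranker-training cap per record (true candidate always kept) |

The defaults are deliberately on the generous side for real patent-scale
data. The examples, tests and the acceptance script use `hidden_dim = 32`,
`depth = 2`, `K = 10`, `max_edits = 3` with a few hundred synthetic
records — these sizes are where the synthetic families saturate, and they
keep a full two-stage run in the minutes range on one CPU.

## Numerical and design choices

* **Bond-order alphabet** is fixed to {0, 1, 1.5, 2, 3}; aromatic bonds
  carry 1.5. Implicit hydrogens are recomputed from charge-adjusted default
  valences whenever edits touch an atom.
* **Charge bookkeeping.** Edits never change formal charges directly, but a
  small neutralization rule set keeps edited structures sanitizable: a
  halogen stripped of its bond becomes a halide anion, an alkoxide that
  gains a bond loses its charge, an ammonium that drops to three bonds is
  neutralized, a neutral nitrogen reaching four bonds is quaternized.
* **Valence filter.** OpenBabel is permissive about hypervalence, so the
  filter checks an explicit per-element maximum (C 4, N 3/N⁺ 4, O 2/O⁻ 1,
  P 5, S 6, halogens 1, B 3) before the structure is also required to
  canonicalize cleanly.
* **Fragment policy.** A candidate product keeps exactly the connected
  components containing at least one edit-participating atom; recorded
  products in the synthetic data follow the same convention (so an SN2
  record's product is `ether.[Br-]`), which makes exact-match comparison
  between candidates and records well defined. Candidates whose retained
  fragments are unchanged from the reactants are dropped.
* **Exact match** compares OpenBabel canonical SMILES with atom maps
  stripped and fragments sorted; stereo markers are stripped before
  comparison by default (configurable), since the model neither predicts
  nor scores stereochemistry.
* **Ties.** Top-*K* selection breaks likelihood ties by (i, j, order)
  ascending over map ids; final ranking breaks score ties by preliminary
  score, then lexicographic product SMILES. All orderings are
  deterministic, and every training entry point honors a single seed.
* **Gradients** are hand-written reverse-mode matrix code validated against
  central finite differences (relative tolerance 1e-4 with an absolute
  floor of 1e-6 for near-zero entries).

## The synthetic generator

Real atom-mapped patent corpora are large, heterogeneous and external; the
generator instead emulates their statistical shape at desk scale: small
reaction centers (1–3 edits), decorated substrates drawn from a scaffold
grammar, spectator substituents, inert distractor species appended to the
reactant pool (default probability 0.3), counterion/base tokens in the
reagent field, and — crucially — a reagent-conditional family. Six families
ship: SN2 halide substitution, Fischer esterification, amide coupling,
base-conditional O- vs N-alkylation of amino alcohols (the same substrate
pair gives the ether with the hydroxide token and the amine product
without it), Suzuki-like biaryl coupling (3 edits, boron reagent), and a
single-edit decarboxylation-like C–C cleavage. Records are constructed by
*applying* the family's ground-truth edits, so every record round-trips by
construction, and the independent graph-diff extractor is tested against
that ground truth.

What the generator does **not** emulate: stereochemistry, yields,
competing side reactions, noisy or incomplete atom mapping, and the long
tail of rare reaction types in real data. Passing tests on these fixtures
demonstrates that the machinery — edit extraction, scoring, enumeration,
ranking, conditioning on disconnected reagents — is correct and can be
learned end to end; it does not certify accuracy on patent-scale
chemistry, whose headline numbers require the external corpus and
GPU-scale training.

## Worked example

```{r example, eval = FALSE}
records <- generate_reactions(c("sn2", "esterification"), n = 500, seed = 2024)
splits <- family_split(records, c(0.8, 0.1, 0.1), seed = 7)

cfg <- wln_config(hidden_dim = 32, depth = 2, K = 10, max_edits = 3,
                  epochs = 25, lr = 2e-3, batch_size = 8, seed = 101)
m1 <- train_reactivity(splits$train, cfg, valid = splits$valid)
m2 <- train_ranker(splits$train, m1,
                   wldn_config(hidden_dim = 32, depth = 2, epochs = 5,
                               lr = 2e-3, max_train_candidates = 10, seed = 102))
pipe <- rxn_pipeline(m1, m2)

predict(pipe, "BrCC.[O-]CC", top_n = 3)
preds <- lapply(splits$test, function(r) predict(pipe, r))
topk_accuracy(preds, splits$test)
```

## Known limitations

* Atom-mapping inference is out of scope: training reactions must arrive
  mapped; unmapped input is supported at predict time only (maps are
  assigned internally).
* Stereocenters are passed through, never predicted, and ignored by the
  default exact-match comparison.
* Aromaticity is taken from the input notation (lowercase/1.5 orders);
  the package does not re-perceive aromatic systems after edits, which is
  adequate for the shipped families but would need care for reactions
  that create or destroy aromatic rings.
* The R implementation favors clarity over throughput; it is sized for
  thousands, not hundreds of thousands, of reactions.
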