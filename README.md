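# rxnwln

Organic reaction outcome prediction in R, for cheminformatics and
synthesis-planning work: given atom-mapped reactant SMILES, the package
predicts the major product as a ranked probability distribution over
candidate structures.

A reaction is modeled as a set of **graph edits** — (atom, atom, new bond
order) triples over the reactant graph, with order 0 for bond cleavage and
1.5 for aromatic bonds. Prediction runs in two learned stages around a
combinatorial core:

1. A **Weisfeiler-Lehman network** (WLN) embeds every atom by iterated
   neighborhood message passing, adds a **global attention** context so
   disconnected species (bases, catalysts) can influence reactivity, and
   scores every (atom pair, bond order) change with a sigmoid
   cross-entropy-trained logit.
2. The top-*K* changes drive a **focused enumeration**: all combinations of
   up to `max_edits` ≤ 5 changes with distinct atom pairs (at most
   `sum(choose(K, 1:max_edits))` subsets) are applied to the reactants,
   filtered by per-element valence rules and sanitization, and
   deduplicated by canonical SMILES.
3. A **Weisfeiler-Lehman difference network** (WLDN) embeds each candidate,
   pools candidate-minus-reactant atom representation differences into a
   reaction representation, and scores each candidate as a linear head on
   that representation plus the candidate's *preliminary score* (the sum
   of its change likelihoods); softmax cross-entropy training, softmax
   probabilities out. Exact product-SMILES match is the correctness
   criterion throughout.

Molecular I/O is a purpose-built parser/writer for the atom-mapped
reaction-SMILES dialect (`reactants>reagents>products`); canonicalization
and sanitization are delegated to OpenBabel via ChemmineOB. A synthetic
generator ships six reaction families (SN2, esterification, amide
coupling, base-conditional O-/N-alkylation, Suzuki-like coupling,
decarboxylation-like cleavage) with ground-truth edit sets, so the whole
pipeline trains and evaluates without any external download.

## Worked example

```r
library(rxnwln)

records <- generate_reactions(c("sn2", "esterification"), n = 500, seed = 2024)
splits  <- family_split(records, c(0.8, 0.1, 0.1), seed = 7)

cfg <- wln_config(hidden_dim = 32, depth = 2, K = 10, max_edits = 3,
                  epochs = 25, lr = 2e-3, batch_size = 8, seed = 101)
m1 <- train_reactivity(splits$train, cfg, valid = splits$valid)
tail(m1$history, 1)
#>    epoch      loss recall_at_K
#> 25    25 -3.448453           1
```

`recall_at_K = 1` means every held-out record's full edit set sits inside
the model's 10 most likely changes (the reported loss includes the
attention entropy term, so it can go negative). Train the ranker on the
frozen stage-1 model and predict:

```r
m2 <- train_ranker(splits$train, m1,
                   wldn_config(hidden_dim = 32, depth = 2, epochs = 5,
                               lr = 2e-3, max_train_candidates = 10, seed = 102))
pipe <- rxn_pipeline(m1, m2)

predict(pipe, "BrCC.[O-]CC", top_n = 3)
#> <ranked_prediction: 3 candidates>
#>   rank product_smiles probability
#> 1    1    CCOCC.[Br-] 0.982256400
#> 2    2       CC.CCOBr 0.015790649
#> 3    3       C.CCOCBr 0.001522679
```

The rank-1 candidate is diethyl ether plus the displaced bromide — the
expected SN2 outcome — with its edit combination and probability attached.
Held-out accuracy:

```r
preds <- lapply(splits$test, function(r) predict(pipe, r))
topk_accuracy(preds, splits$test)
#>   k accuracy  n
#> 1 1        1 50
#> 2 2        1 50
#> 3 3        1 50
#> 4 5        1 50
```

A file-oriented command-line interface (`generate`, `preprocess`, `train`,
`predict`, `evaluate`) is installed at `inst/cli/rxn.R`; per-atom attention
maps for interpreting *why* an atom was deemed reactive are exported via
`attention_map()` or `cmd_predict(..., attention = TRUE)`.

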