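Package: rxnwln
Title: Reaction Outcome Prediction with Weisfeiler-Lehman Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage prediction of organic reaction products from
    atom-mapped reaction SMILES. A Weisfeiler-Lehman graph convolutional
    network with global attention scores per-atom-pair bond-order changes;
    a focused combinatorial enumerator applies combinations of the most
    likely changes under valence and connectivity constraints to generate
    candidate products; and a Weisfeiler-Lehman difference network ranks
    the candidates into a probability distribution over predicted
    outcomes. Includes reaction SMILES I/O with graph-edit extraction, a
    synthetic reaction-family generator for fully reproducible training
    fixtures, and command-line entry points for preprocessing, training,
    prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
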