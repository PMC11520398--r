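Package: MolConverse
Title: Conversational Molecular Design: Dialogue Corpora, Knowledge-Enhanced
    Pretraining and Evaluation at Desk Scale
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying conversational molecular design, where a user
    describes a target molecule over several turns of natural language and a
    model proposes SMILES structures. The package builds multi-turn dialogue
    datasets from molecule-description parallel corpora using a
    fingerprint-similarity gate on intermediate target molecules, generates
    knowledge-injection pretraining tasks (span-corruption masked language
    modelling, name-to-SMILES mapping correlation, experimental-property and
    spatial-structure question answering), attaches retrieved SMILES prompts
    with answer-leakage removal, trains a small twin encoder-decoder
    sequence-to-sequence model with task prefixes and dual augmentation, and
    scores molecule understanding and generation with exact match, hit@3,
    SMILES BLEU, Levenshtein distance, fingerprint Tanimoto similarities and
    standard text-generation metrics. A synthetic corpus generator with
    verifiable descriptions makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
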