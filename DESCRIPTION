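Package: molgen
Title: Bidirectional Recurrent Generation of Molecular Strings with
    Reinforcement-Learning Fine-Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains LSTM language models over SMILES and SELFIES molecular
    string encodings and generates molecules forward, backward, or
    bidirectionally (FB-RNN and BIMODAL reading schemes), optionally under a
    seed-fragment constraint that is preserved intact in every sample.  A
    variance-reduced REINFORCE loop with batch-mean baseline and entropy bonus
    fine-tunes a trained generator toward a weighted drug-likeness (QED) and
    synthetic-accessibility (SA) reward.  Includes a self-contained SELFIES
    encoder/decoder, analytic and exact counts of the constrained string space
    reachable by unidirectional versus bidirectional generators, and an
    evaluation battery (unique/valid/novel rates, Mann-Whitney and
    Kolmogorov-Smirnov distribution tests, Morgan fingerprints, 2-D
    embedding export).  Chemistry primitives (validity, canonicalisation,
    QED, SA, fingerprints, substructure matching) are delegated to RDKit
    through a persistent Python worker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    processx,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with rdkit and scikit-learn on PATH as
    'python'
Config/testthat/edition: 3
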