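Package: molgraphgen
Title: Sequential Molecular Graph Generative Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sequential generative models for molecular graphs. Molecules are
    built atom-by-atom and bond-by-bond by a learned decoding policy over
    append, connect and terminate actions; two policy architectures are
    provided, a Markov graph network (MolMP) and its molecule-level recurrent
    extension (MolRNN), both built on an edge-conditioned graph convolution
    with a configurable receptive field. Training maximizes an
    importance-weighted likelihood over randomized decoding routes, supports
    conditional codes (scaffold fingerprints, drug-likeness/synthetic
    accessibility pairs, activity labels) for goal-directed generation, and
    ships an evaluation-metric suite (validity, novelty, kernel-density
    KL/JS divergences of property distributions, conditional control
    matrices, enrichment over random, reproduction rate, internal diversity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
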