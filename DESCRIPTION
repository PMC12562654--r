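Package: dynafic
Title: Dynamic Functional Influence Computation on Multi-Layer Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a differential-expression table plus molecular-interaction
    layers (protein-protein interactions, transcription-factor regulation, and
    Gene Ontology semantic similarity) into time-resolved influence trajectories
    via discrete network diffusion with regulatory amplification, and combines
    the diffused influence with functional-context metrics and degree centrality
    into composite per-gene scores. Includes trajectory clustering with
    silhouette selection, a one-dimensional Wasserstein distance with a
    permutation null, stability-volatility and functional-heterogeneity
    indices, and synthetic-data generators emulating STRING-, TRRUST-, OBO-,
    and GTEx-style inputs so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
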