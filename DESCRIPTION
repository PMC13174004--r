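Package: ccibench
Title: Simulation-Based Benchmarking of Spatial Cell-Cell Interaction Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for cell-cell interaction (CCI) inference
    from spatial transcriptomics. Provides two ground-truth-embedding
    simulators (single-cell resolution with Voronoi cell-type territories and
    k-nearest-neighbor sender-receiver neighborhoods; spot-level resolution
    with hexagonal scaffolds and 12-cell spot mixtures), negative-binomial
    expression models fitted from a single-cell reference, a ligand-receptor
    database harmonizer (normalization, intersection, single-chain and
    feasibility filtering), an evaluation suite (confusion counts, precision,
    recall, F1, specificity, score normalization, Jaccard consistency,
    spatial-proximity rank profiles), and pathway-level scoring of interaction
    calls against literature-curated silver standards via hypergeometric
    enrichment with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
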