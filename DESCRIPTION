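Package: bpnet
Title: Gene Set Enrichment and Biological Process Network Inference
Version: 0.1.0
Authors@R: person("BPN", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for two-condition transcriptomic analysis:
    sample-level hierarchical clustering diagnostics with Newick export,
    from-scratch gene set enrichment analysis (signal-to-noise ranking,
    weighted running-sum enrichment score, gene-set permutation null,
    Benjamini-Hochberg FDR, leading edges), STRING-style interaction
    network filtering, and a Markov chain Monte Carlo sampler that links
    enriched gene sets through protein-interaction support among perturbed
    genes. Includes a synthetic data generator with planted differential
    gene sets and planted inter-set connectivity so every stage can be
    validated without external downloads, plus readers and writers for
    GCT, CLS, GMT, edge-list TSV, SIF and GraphML formats.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ape,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
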