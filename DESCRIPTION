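Package: czbkit
Title: Survey and Quantitative Analysis Toolkit for Chemoreceptor
    Zinc-Binding (CZB) Domains
Version: 0.1.0
Authors@R:
    person("czbkit", "maintainers", email = "maintainers@czbkit.dev",
           role = c("aut", "cre"))
Description: Identifies chemoreceptor zinc-binding (CZB) domains in protein
    sequences by their conserved 3His/1Cys zinc core and seven-residue
    alpha-3 motif, classifies CZB-containing proteins into the seven
    canonical domain architectures (soluble and membrane-bound
    chemoreceptors, diguanylate cyclases with and without EAL domains,
    EAL-CZB, CheW-CZB, and CZB-only), computes per-column conservation and
    motif logo matrices from multiple alignments, and aggregates
    architecture calls to species-level co-occurrence summaries.  Also
    implements the quantitative models used in CZB biochemistry and
    phenotyping: Hill dose-response fits for hypochlorous-acid oxidation,
    quadratic tight-binding fits for chelator titrations, linear zinc
    inhibition, crystal-violet biofilm normalization, Congo red colony
    color segmentation, and pellicle intensity-profile quantification.  A
    synthetic-data module generates labeled inputs for every stage so the
    full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
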