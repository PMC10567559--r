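Package: assemblyr
Title: Assembly Theory Toolkit: Assembly Indices, Pathways and Selection Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembly theory on discrete objects. Computes exact
    assembly indices and shortest assembly pathways for strings, homopolymers
    (minimal addition chains) and small molecular graphs (bond-based
    branch-and-bound with reuse of duplicated substructures); evaluates the
    ensemble assembly equation combining assembly indices with copy numbers;
    simulates forward assembly processes (undirected and directed polymer
    exploration with joint assembly spaces and exploration ratios); and models
    discovery/production dynamics with power-law selection kinetics, timescale
    regimes and ensemble assembly over time. Includes readers and writers for
    the standard interchange formats (FASTA, SDF/SMILES, TSV, GraphML, JSON,
    YAML) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    optparse,
    deSolve,
    ChemmineR,
    Biostrings,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
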