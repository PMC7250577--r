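Package: chimeraTrace
Title: Diagnosing the Chimeric Origin of Two-Domain Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for diagnosing whether a two-domain gene arose
    as a chimera of a vertically inherited eukaryotic domain and a
    horizontally transferred bacterial domain. Provides iterative
    profile-based discovery of two-domain orthologs, sliding-window taxonomic
    provenance profiling, per-domain sequence similarity networks, and
    per-domain maximum-likelihood phylogenetics with constrained-topology
    SOWH parametric-bootstrap tests, together with a seeded simulator of
    ground-truthed chimeric and null (vertical-descent) scenarios used to
    validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
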