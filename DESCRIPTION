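Package: clonetracker
Title: Graph-Based Clonal Tracking of Viral Vector Integration Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Incremental clonal tracking for gene-therapy integration-site
    (IS) studies. Imports per-sample IS cluster records, stores them in a
    typed property graph (sample, subg, pos and label nodes), links clones
    across samples with four genomic matching rules at sample insertion
    time, and exports the clone-by-sample tracking matrix with read, shear
    (sonication fragment), UMI and combined quantifications. Ships a
    dilution-standard assay simulator with known ground truth, a
    brute-force all-versus-all tracking oracle for validation, GraphML
    persistence and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
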