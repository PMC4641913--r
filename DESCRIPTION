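Package: reactnorm
Title: Expression Reaction Norms from Two-Condition RNA-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives co-regulated gene groups from a two-condition RNA-seq
    time course of digital (count-based) expression libraries. Implements
    RPKM quantification with a read-count detection filter, per-time-point
    exact-test differential expression for unreplicated count libraries
    (conditional binomial test with Benjamini-Hochberg FDR control and
    fold-change calling), reaction-norm profile construction with histogram
    normalization, co-expression clustering via a batch self-organizing map
    on a hexagonal lattice followed by k-means grouping of codebook vectors
    and a coherence filter, Fisher's exact Gene Ontology over-representation
    per cluster, and 2^-ddCt qRT-PCR relative quantification with
    cross-platform concordance scoring. Includes a synthetic-data generator
    with planted temporal response archetypes so the whole pipeline can be
    exercised and scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
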