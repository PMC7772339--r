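Package: mossmicrobiota
Title: Downstream Analysis of Moss-Associated 16S rRNA Gene OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for peatland moss microbiome surveys based on
    16S rRNA gene OTU count tables. Provides a SummarizedExperiment-backed OTU
    table container with taxonomy-aware and abundance-based filtering,
    inverse Simpson diversity with pairwise group tests and compact letter
    displays, Spearman-correlation community dendrograms with the
    agglomerative coefficient, correspondence analysis and (partial) canonical
    correspondence analysis implemented from first principles with
    permutation inference, variance inflation factors and per-variable
    variance partitioning, prevalence-threshold core-microbiome construction
    with abundance contributions, and a paired endophyte-versus-epiphyte OTU
    screen using Monte-Carlo chi-square contingency tests. A synthetic-study
    generator emulates the nested sampling design of a two-peatland-system
    survey (Amblystegiaceae fens versus Sphagnum bogs) with planted core,
    system-specific and endophyte-enriched OTUs so that every stage of the
    pipeline has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    ape,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
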