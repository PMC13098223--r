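Package: viromeflow
Title: Viral Genome Catalogs and Gut Virome Community Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds species-level viral operational taxonomic unit (vOTU)
    catalogs from assembled metagenomic contigs and analyses virome community
    structure. Implements contig retention filtering and terminal-repeat
    detection, merged-local-alignment average nucleotide identity (ANI) with
    greedy centroid clustering at the 95/85 species criterion, amino-acid
    identity (AAI) gene-sharing graphs clustered with an in-package Markov
    Clustering algorithm at genus and family ranks, total-ANI (tANI)
    single-linkage clustering, read-recruitment abundance under identity,
    aligned-fraction and breadth filters, and community statistics: richness,
    core virome, species accumulation curves, Bray-Curtis dissimilarity,
    PERMANOVA, principal coordinates analysis, rank tests and negative
    binomial richness models. A synthetic-data generator produces
    hierarchically diverged viral lineages, decorated contigs, alignment
    tables and reads with known ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    igraph,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
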