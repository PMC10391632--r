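Package: bmpc
Title: Bone-Marrow Plasma-Cell Single-Cell QC, Cluster Stability, and BCR Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-cell studies of human bone-marrow
    antibody-secreting-cell maturation. Implements cell- and gene-level
    quality-control filters, Rand-Index cluster-stability scoring over a
    clustering-parameter grid, marker thresholding and preranked weighted
    Kolmogorov-Smirnov enrichment with pathway U-scores, transcription-factor
    cluster assignment with interaction-network filtering, and a B-cell
    receptor repertoire stage: clonal-lineage clustering by CDR3 homology,
    somatic-hypermutation profiling with replacement/silent classification,
    Morisita-Horn repertoire connectivity, and an ANOVA/Tukey permutation
    test for mutation-frequency differences. A synthetic-data generator
    produces paired expression and repertoire datasets with full ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    seqinr,
    withr
Config/testthat/edition: 3
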