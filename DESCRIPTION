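Package: azscreen
Title: Multi-Scale Transcriptome Screen for Abscission-Zone-Specific Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying abscission-zone-specific, abscission-timed
    genes from unreplicated tag-count sequencing libraries. Implements the
    exact Audic-Claverie two-library count comparison with Bonferroni
    adjustment, a four-step multi-scale screen combining an ethylene
    time-course, between-tissue specificity filtering and concordance with
    natural ripening-stage profiles, hierarchical clustering and rule-based
    shape classification of expression profiles, RPKM/per-million abundance
    normalization, qPCR primer-efficiency estimation from serial dilutions,
    and a seeded synthetic count-data generator with planted effects for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Clustering, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
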