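Package: igea
Title: Imaging Genetic Enrichment Analysis of Gene Set x Brain Circuit Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional enrichment analysis for brain imaging genetics.
    Builds candidate gene set x brain circuit (GS-BC) modules by two-way UPGMA
    clustering of a gene x ROI expression matrix with half-height dendrogram
    cuts, scores module co-expression with averaged Fisher z-transformed
    Pearson correlations, maps SNP-level GWAS summary statistics to gene-level
    p-values by a minimum-p window rule, tests each module for
    over-representation of significant gene-QT associations with the
    hypergeometric upper tail, and evaluates the overall number of significant
    modules against label-permuted GWAS results with a Student-t tail
    approximation. Includes a seeded synthetic-data generator with planted
    co-expression blocks and enriched p-value blocks so the whole pipeline is
    testable without restricted imaging-genetics data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
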