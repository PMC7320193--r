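Package: lhcomplex
Title: Locus Heterogeneity and Protein Complex Intersection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how often mutations in different genes that cause the
    same disease (locus heterogeneity) hit members of the same protein
    complex. Parses OMIM-style morbid maps, phenotypic-series tables and
    OBO ontologies; prunes Gene Ontology cellular-component "complex" terms
    to an analysis catalog; measures disease/phenotypic-series versus
    complex overlap with the Jaccard coefficient; assesses significance
    with permutation null models and Z-scores; promotes complex members to
    presumptive disease proteins via mouse-ortholog phenotype matching; and
    separates univocal from redundant series-complex relations. Includes a
    synthetic-universe generator with a planted ground truth so the whole
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    readr,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
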