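Package: degscope
Title: Differential Expression Classification, GO Over-Representation and
    Cross-Dataset Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes from processed expression tables (log2 fold
    change and p-value per gene) into up-regulated, down-regulated and not
    differentially expressed sets, renders volcano plots, performs Gene
    Ontology over-representation analysis per direction and namespace using
    a hypergeometric test with Benjamini-Hochberg false discovery rate
    control, parses OBO ontologies and NCBI gene2go annotations, and
    compares two expression datasets via a 3x3 expression-class contingency
    table. Ships a deterministic synthetic-data generator producing toy
    ontologies, annotation files and expression tables with planted signal
    so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ggplot2,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'deg-classify.R'
    'dataset-compare.R'
    'go-ontology.R'
    'go-annotations.R'
    'enrichment.R'
    'expression-io.R'
    'synthetic.R'
    'plots.R'
    'pipeline.R'
    'utils.R'
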