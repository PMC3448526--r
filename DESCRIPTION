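Package: phenomap
Title: Cross-Species Phenotype Ontology Alignment and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns a pair of species-specific phenotype ontologies (such as the
    Human Phenotype Ontology and the Mammalian Phenotype Ontology) by two routes:
    lexical seed matching of concept names and synonyms followed by taxonomic
    closure, and structural entity-quality (EQ) subsumption over shared anatomy
    and quality support ontologies. Provides the five-way overlap classification
    of the two methods' mapping sets, annotation translation across ontologies,
    cosine phenotype similarity, and pooled ROC/AUC evaluation of gene-disease
    prioritization against gold-standard associations. Includes a seeded
    synthetic-data generator that emulates the full input bundle (OBO ontologies
    with EQ definitions, genotype-phenotype and disease-phenotype annotations,
    orthology, gold associations) with controllable definition coverage, label
    sharing and annotation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
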