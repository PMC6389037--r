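Package: comorbinet
Title: Network-Based Prioritization of Candidate Genes for Disease Comorbidity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds two-disease comorbidity gene networks by intersecting
    typed gene/protein association networks, extracts the genetic regulatory
    subnetwork, and prioritizes candidate comorbidity genes by aggregating
    ten ranking criteria: two external prioritizer rankings, involvement in
    enriched Gene Ontology biological processes, centrality in the complete
    and regulatory networks, specificity of gene-process associations
    (Welch t-test with Bonferroni correction), and four binary criteria
    based on whole-blood eQTL SNPs with common European minor alleles and
    their disease associations. Includes graph structure analysis
    (degree/closeness/betweenness centrality, fundamental cycle basis),
    hypergeometric/EASE over-representation tests, gene-subset statistics,
    literature co-mention tests, and a seeded synthetic knowledgebase
    generator with planted comorbidity genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
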