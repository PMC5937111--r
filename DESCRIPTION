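Package: ppiscreen
Title: Hub-Bottleneck Screening and Module Analysis of Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A screening cascade for candidate biomarker discovery from
    protein-protein interaction (PPI) networks built around differentially
    expressed gene lists. Implements degree and Brandes betweenness
    centrality ranking, top-k hub and bottleneck selection with
    hub-bottleneck intersection, MCODE molecular complex detection with
    the canonical vertex-weighting and seeded-expansion procedure,
    hypergeometric over-representation analysis with Holm (Bonferroni
    step-down) correction and Cohen's kappa term grouping, and a
    degree-cutoff biomarker panel selector. Ships the printed
    differentially expressed protein tables of a laryngeal carcinoma
    proteomics screen as plain-text fixtures, plus a synthetic scale-free
    interactome generator with planted dense modules and
    planted-enrichment annotation catalogs so every pipeline stage is
    testable without external database downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
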