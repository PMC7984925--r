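Package: qmnet
Title: Network-Pharmacology Quality-Marker Discovery for Herbal Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for selecting quality markers of multi-herb preparations
    by network pharmacology. Starting from a table of quantified components
    (selected-ion-monitoring metadata) and per-compound target-gene predictions,
    the package intersects compound targets with a disease gene set, builds the
    heterogeneous prescription-component-disease-gene-pathway network, screens
    components by degree centrality against a threshold, and performs
    hypergeometric over-representation analysis of the common target genes with
    Benjamini-Hochberg correction. Includes Tanimoto-similarity target
    prediction against a reference ligand library, ESI adduct m/z consistency
    checks for monitoring-ion tables, and a synthetic-data generator with
    planted ground truth for end-to-end validation. Bundled example data
    describe the eight-herb decoction HXJTY (Huo-Xue-Jiang-Tang Yin) studied
    against type 2 diabetes mellitus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
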