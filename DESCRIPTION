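Package: coexdiff
Title: Weighted Co-Expression Networks and Cross-Network Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from expression
    matrices (soft-thresholded correlation, topological overlap, scale-free
    topology criterion), detects and annotates co-expression modules by
    hierarchical clustering with eigengene merging, performs hypergeometric
    over-representation analysis against GMT gene-set collections, and
    quantifies divergence between networks built from different datasets:
    gene-set Venn decomposition, module cross-tabulation, scaled-connectivity
    rank differences, correlated-neighbor lookup and druggability rank joins.
    Includes a latent-factor simulator with planted modules and hub genes so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
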