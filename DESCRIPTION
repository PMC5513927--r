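Package: sfaudit
Title: Auditing the Within-Network Strength Fraction for Spatial Confounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compute the within-network "strength fraction" (SF) of a
    tissue-tissue gene-expression correlation graph, its label-permutation
    null distribution, and a battery of spatial-proximity diagnostics and
    corrections: same-tissue-class edge removal, minimum-distance edge
    filtering, and linear distance residualization. Includes a generator for
    synthetic, spatially autocorrelated expression data over 3D point clouds
    with contiguous network labels and Voronoi tissue parcellations, and a
    "null network" experiment that tests whether randomly placed, size-matched
    contiguous clusters are as significant as real networks. Designed to show
    how spatial autocorrelation inflates permutation-test significance when
    sample labels are treated as exchangeable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
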