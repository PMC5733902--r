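Package: windowscape
Title: Multi-Scale, Multi-Site Sliding-Window Landscape Genetics
Version: 0.1.0
Authors@R:
    person("windowscape", "developers", email = "windowscape@example.org",
           role = c("aut", "cre"))
Description: Tests isolation-by-resistance (IBR) hypotheses against
    isolation-by-distance (IBD) across thousands of circular study areas that
    vary in diameter and center (sliding windows). Provides individual-based
    Bray-Curtis genetic distances from 0/1/2-coded microsatellite genotypes,
    commute-time resistance distances on raster conductance surfaces via the
    graph Laplacian, partial Mantel permutation tests with an explicit support
    criterion, commonality analysis of distance-matrix regression, empirical
    semivariograms, deme summary statistics (Weir-Cockerham Fst and Fis,
    rarefied allelic richness), inverse-distance-weighted mapping of support,
    and a forward-time landscape genetic simulator for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
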