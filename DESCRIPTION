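Package: marinerealms
Title: Global Marine Bioregionalization from Species Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Delimits statistically supported, spatially contiguous marine
    biogeographic realms from point occurrence records. Occurrences are
    cleaned, deduplicated into latitude-longitude grid cells (c-squares
    style), converted to binary presence matrices, and compared with
    presence-absence beta-diversity indices (Jaccard, Sorensen, Simpson
    beta-sim). Cells are clustered by group-average (UPGMA) agglomeration,
    tested for multivariate structure with SIMPROF and ANOSIM permutation
    tests, and progressively cut at low percent-similarity thresholds into
    nested realms with contiguity filtering and small-enclave absorption.
    Per-realm endemicity statistics, widespread-species rankings, bootstrap
    co-clustering support, and a synthetic-data generator with planted realm
    structure for end-to-end validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
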