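Package: recpot
Title: Spatial Multi-Criteria Mapping of Nature-Based Recreation Potential
Version: 0.1.0
Authors@R:
    person("recpot", "developers", email = "recpot@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping an integrated nature-based recreation
    potential index over gridded landscapes. Indicator weights are derived by
    fusing subjective analytic-hierarchy-process (AHP) weights with objective
    entropy weights; polarity-aware min-max standardization and weighted
    raster overlay produce a potential surface in [0,1], which is cut into
    ordinal levels (fixed or geometric-interval breaks). Downstream analyses
    cover epoch-to-epoch level transition matrices, zonal contrasts
    (protected vs non-protected areas, division-line halves), and
    segmented-regression detection of an elevation threshold in the index.
    A synthetic-landscape generator with planted, recoverable parameters
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
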