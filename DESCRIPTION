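Package: fluctasym
Title: Fluctuating Asymmetry of Bilateral Landmark Data with Habitat and
    Genetic Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of developmental instability in bilaterally
    paired structures. Reads replicated two-dimensional landmark data in TPS
    format, performs matching-symmetry generalized Procrustes alignment,
    fits Procrustes and centroid-size ANOVAs with nested measurement-error
    strata, and derives per-individual fluctuating-asymmetry indices
    (Mahalanobis shape scores and signed/absolute centroid-size
    differences). Companion modules compute microsatellite summaries
    (observed heterozygosity, Weir-Cockerham f, exact Hardy-Weinberg and
    linkage-disequilibrium tests), scale-of-effect radii and buffer-based
    habitat amount on binary rasters, and the association battery linking
    asymmetry to habitat and genetic factors (Pearson correlations, group
    tests, likelihood-ratio tests against an intercept-only model, and
    Bonferroni control). A synthetic-data generator reproduces the full
    replicate structure of such studies so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
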