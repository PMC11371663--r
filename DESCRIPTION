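Package: nichelegacy
Title: Climatic Niche Overlap and Similarity Testing for Paired Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares the realized climatic niches of paired taxa (for
    example regionally extinct versus extant congeners of one family) in a
    shared available climate space. Provides an environmental PCA over
    background climate cells, availability-corrected kernel occupancy grids,
    Schoener's D overlap, directional niche similarity and difference
    randomization tests with study-wide multiple-comparison adjustment,
    per-variable kernel density overlap, two niche volume estimators
    (Schoener's D against availability and 95 percent highest-density-region
    area ratios), and a synthetic landscape and occurrence generator with
    known niche structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
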