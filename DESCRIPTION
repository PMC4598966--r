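Package: spaccess
Title: Spatial Accessibility Indices from Distance-Distribution Inflection Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying geographic access to home-visit health
    services from point data. Computes nearest-provider distances, bins them
    into fixed-width groups, fits a polynomial trend curve and extracts two
    catchment indices from derivative sign changes: the profit-willing
    distance (PWD, the first interior local maximum of the fitted curve) and
    the tolerance-limited distance (TLD, the first post-peak concavity
    change). Includes buffer-ring provider-multiplicity tables with two-level
    percentage conventions, rural-urban disparity summaries, cohort
    comparison statistics from printed contingency and summary tables, and a
    seeded synthetic scenario generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
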