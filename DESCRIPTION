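Package: ringpatterns
Title: Radial Growth Patterns and Disturbance Reconstruction from Tree Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the disturbance history of old-growth boreal stands
    from annual ring-width series. Tree-level series are resampled into
    20-segment growth profiles and clustered with restarted k-means, choosing
    the number of radial growth patterns by the simple structure index.
    Percent growth change over adjacent 10-year windows detects growth
    releases and suppressions, which are aggregated into smoothed site
    chronologies and peak intervals. Stand-structure utilities provide
    dominant height, canopy-layer classification, stand summaries and the
    cohort basal area proportion, and permutation tests link growth patterns
    to canopy layers and tree attributes. A seeded outbreak-driven simulator
    generates ring-width series and plot inventories with known pattern,
    release and cohort truth so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
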