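Package: vitivuln
Title: Climate-Change Vulnerability Assessment for Wine Geographical Indications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated exposure-sensitivity-adaptive-capacity vulnerability
    assessment for winegrowing regions (geographical indications). Computes the
    viticultural bioclimatic indices (Huglin heliothermal index, Cool Night
    Index, Riou Dryness Index) from monthly climatologies, derives regional
    climate-change exposure from index deltas, estimates cultivation-area
    weighted bioregional climate ranges of grape varieties and the resulting
    regional sensitivity and positive-effect shares, aggregates a 15-indicator
    adaptive-capacity composite (percentile-winsorized scaling, optional
    analytic-hierarchy-process weighting with consistency gating), and
    classifies regions into vulnerability levels and groups by tertile rules.
    Includes a seeded synthetic-data generator emulating all pipeline inputs
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
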