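Package: mindu
Title: Macroinvertebrate Multimetric Indices for Urban River Biomonitoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and applying macroinvertebrate-based
    multimetric indices (MMIs) of water quality for rivers under urban
    pollution. Delineates stations along a physicochemical impact gradient
    by principal component analysis, computes candidate community metrics
    (abundance, composition, richness, diversity, and fuzzy-coded trait
    metrics), screens metrics for sensitivity, seasonal stability and
    redundancy with nonparametric tests, derives quartile-based 5/3/1
    scoring thresholds from least-impacted stations, and aggregates metric
    scores into an index with water-quality classes. Ships the published
    Multimetric Index for Niger Delta Urban rivers (MINDU) as a
    ready-to-apply scorer, plus a synthetic-survey generator for testing
    the full workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
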