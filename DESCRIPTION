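Package: fiberscan
Title: Quantification of Protein Distributions on Stretched Chromatin Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peak-based quantification of fluorescence line-scan profiles from
    stretched chromatin fibers. Calls intensity peaks with fixed gray-value
    thresholds, measures nearest-peak distances and co-localization between
    channels, derives centromere-domain metrics (domain sizes, peak-count and
    domain-size ratios, three-category peak classification, spreading
    distances) and two-protein co-spreading patterns, and aggregates fibers
    per construct with normality-guided two-sample tests and FDR adjustment.
    Includes a synthetic-fiber generator with per-peak ground truth so the
    whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    readr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
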