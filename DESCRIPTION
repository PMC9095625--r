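Package: isoclim
Title: Stable-Isotope Tree-Ring Chronologies and Multi-Proxy Climate Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building annually resolved stable carbon and oxygen
    isotope tree-ring chronologies (pyrolysis and Suess-effect corrections,
    juvenile-ring exclusion, pooled site means with replication statistics
    and EPS), calibrating proxy-climate transfer functions against monthly
    station records, verifying them with split-period skill statistics
    (RE, CE, Gleichlaeufigkeit, Durbin-Watson, first-difference tests),
    reconstructing local summer climate over the Common Era, and compositing
    mixed-resolution proxies (tree rings and decadal lake sediments) into
    regional reconstructions with averaged-over-orderings variance
    partitioning. Includes a synthetic-data generator that emulates the
    coupling structure of high-elevation larch isotope records so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    lmtest
Config/testthat/edition: 3
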