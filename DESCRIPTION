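Package: pelagicarb
Title: Pelagic Calcium Carbonate Standing Stock, Production and Export Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a pelagic calcium carbonate budget from plankton
    observations. Converts net-tow shell counts, foraminiferal picked weights and
    coccolithophore filter counts into per-taxon CaCO3 standing stocks; propagates
    flat-prior turnover-time uncertainty into daily and seasonally corrected annual
    production with Monte-Carlo simulation; provides skew-robust basin statistics
    (zero-truncated kernel density, bootstrap, sample skewness) for biomass
    compilations; extrapolates station production globally through a satellite-PIC
    regression with area-weighted integration; and compares production against
    sediment-trap export fluxes. A synthetic-data generator emulates every input
    with known ground truth so the full analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
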