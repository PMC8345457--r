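Package: lagopop
Title: Landscape Population Model for Pesticide Risk to Herbivorous Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic, individual-based population model for assessing the
    risk of pesticide applications to large herbivorous mammals (wild rabbit,
    brown hare) at the landscape scale. Couples nest-based daily demography
    (binomial deaths, Poisson seasonal births, age-group promotion) to a field
    and feeding-area exposure model (residue-per-unit-dose deposition,
    first-order dissipation, dietary weighting) and to clamped linear
    dose-(time-)response functions derived from regulatory endpoints (LD0,
    LD50, NOAEL, LOAEL with interspecies factors). Effects on survival and
    reproduction are combined across pesticides by independent-survival
    multiplication and applied with month lags driven by time-weighted-average
    exposure windows. Includes replicated simulation with confidence-interval
    summaries and bundled case-study scenarios for glyphosate and bromoxynil.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
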