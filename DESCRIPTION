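Package: fertghg
Title: Greenhouse Gas Accounting for Synthetic Nitrogen Fertiliser Supply Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Full-chain greenhouse-gas accounting for synthetic nitrogen
    fertilisers: empirical estimation of direct soil N2O emission factors from
    paired-plot field measurements, country-level accounting of manufacturing,
    transport, direct and indirect field emissions and urea hydrolysis in
    CO2-equivalents, Monte Carlo propagation of emission-factor uncertainty,
    and derived use-trend indicators (carbon intensity, per-capita footprint,
    fertilisation rate, growth rates). Includes a synthetic-data generator that
    emulates the structure of the activity and field datasets so the whole
    pipeline runs without restricted inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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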