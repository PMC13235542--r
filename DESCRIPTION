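Package: nhxiso
Title: Ammonia Volatilization, Acid Trapping, and Nitrogen Isotope
    Systematics of Sulfidic Cave Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the transfer of ammonia from circumneutral sulfidic
    streams to extremely acidic cave-wall droplets and the nitrogen
    isotope signatures that transfer imprints. Provides NH4+/NH3
    acid-base speciation with van't Hoff temperature corrections,
    Henry's-law gas-water equilibrium predictions of NH3(g) mixing
    ratios, a chained equilibrium isotope-fractionation model for
    volatilized and acid-trapped ammonia, Rayleigh reservoir-evolution
    checks, two-endmember delta-15N mixing, total-reduced-nitrogen
    isotope mass balance, and Gibbs-energy favorability of ammonia
    oxidation as a function of pH and ammonium concentration. Includes a
    synthetic field-campaign generator and an end-to-end analysis
    pipeline that emits a structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
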