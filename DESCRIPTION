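Package: reeflux
Title: Flux Balance and Multi-Omics Analysis of the Rare-Earth Methanol
    Dehydrogenase Switch in Methanotrophs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the lanthanide (rare-earth element) switch
    between the calcium-dependent MxaFI and lanthanum-dependent XoxF
    methanol dehydrogenases in methanotrophic bacteria such as
    Methylomicrobium alcaliphilum 20Z. Provides a reduced core
    stoichiometric model of C1 metabolism with both methanol-oxidation
    routes and a cytochrome-linked formaldehyde-to-formate branch, flux
    balance and flux variability analysis with a branch-fraction
    constraint and energetic calibration, chemostat physiology
    calculators (yields, specific consumption rates, off-gas balances),
    decision rules for transcriptomic, spectral-count proteomic and
    metabolomic comparisons, and synthetic-data generators that emulate
    two-condition chemostat multi-omics experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
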