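Package: vibriopassage
Title: Bottleneck Population Dynamics and Selection Inference for
    Squid-Vibrio Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic computations for serial-passage
    experimental evolution of Vibrio fischeri through its squid host:
    a closed-form (Wahl-Gerrish) survival approximation for rare
    beneficial mutants arising between periodic bottlenecks, a
    lineage-resolved stochastic simulator of inoculum growth, host
    recruitment, and daily venting/regrowth cycles, mutation-supply
    calculations for a focal locus under population expansion,
    estimation of Malthusian parameters and selection coefficients from
    marked-strain competition counts, exact Fisher-Pitman permutation
    and exact binomial tests, and synthetic-data generators that emulate
    dilution-plating competition assays with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
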