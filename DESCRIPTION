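Package: dbiperm
Title: Dragonfly Biotic Index Scores and a Permutational Conservation-Value Potential
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for freshwater bioassessment with the Dragonfly Biotic
    Index (DBI). Manages and validates species checklists carrying the three
    DBI subindices (distribution, threat, sensitivity), resolves site samples
    against a regional species pool, and computes DBI_sum and DBI_mean. Adds
    a permutational DBI potential for conservation prioritization: the
    percentile of a community's DBI_sum among randomly assembled communities
    of the same richness, drawn from the pool without replacement with
    probability weights x^-DBI. Includes occupancy-based calibration of the
    weight base x, a simulated-scenario evaluator, and a Kolmogorov-Smirnov
    stability diagnostic for the potential.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
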