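Package: meiocross
Title: Crossover Mapping and Interference Analysis for Backcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps meiotic crossovers in low-coverage sequenced backcross
    (BC1) populations and quantifies crossover interference and
    heterochiasmy. Provides marker and sample quality-control filters for
    shallow genotyping-by-sequencing variant matrices, sliding-window modal
    genotype smoothing, crossover breakpoint calling, 1-Mb recombination
    landscapes, inter-crossover distance permutation tests, coefficient of
    coincidence curves with LOESS fits, nested ANOVA sex/genotype
    comparisons, and a cytological focus colocalization statistic. A
    gamma-renewal meiosis simulator with a sequencing observation model
    generates fully synthetic BC1 populations for validation by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
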