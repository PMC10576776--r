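Package: segclock
Title: Stochastic Amplitude-Threshold Analysis of Segmentation Clock Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of variable somite-segmentation phenotypes in
    zebrafish segmentation-clock mutants. Provides a stochastic amplitude-threshold
    simulator of per-cycle boundary outcomes, synthesis and analysis of
    determination-front kymographs (line-of-interest profiles, Savitzky-Golay
    smoothing, windowed trough-to-peak wave-amplitude extraction, normalization
    against intact boundaries), penetrance, expressivity and consecutive- and
    left-right-boundary correlation statistics for binary metameric phenotype
    tables, and spatial Pearson correlation of two-gene smFISH transcript fields
    sliced along stripe-parallel planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tiff,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
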