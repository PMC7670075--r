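Package: qtlmicro
Title: Dissecting eQTL Micro-Architecture with Recombinant Inbred and
    Introgression Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the micro-architecture of expression
    quantitative trait loci (eQTL) by contrasting recombinant inbred line
    (RIL) and introgression line (IL) panels, modelled on the C. elegans
    N2 x CB4856 cross. Provides simulation of mosaic RIL and single-segment
    tiling IL genotype panels, generation of expression data under
    configurable QTL architectures, parent-referenced z-score and log2-ratio
    transforms, broad-sense heritability with permutation significance
    thresholds, single-marker eQTL mapping with cis/trans classification,
    per-strain eQTL confirmation and trans-band replication statistics,
    simulation of eight trait architectures to obtain relative-heritability
    (log2 IL:RIL variance ratio) distributions, and a two-interval linear
    deconvolution of observed ratios into additive versus balanced
    closely-linked components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
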