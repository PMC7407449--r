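Package: flymap
Title: Forward-Genetics Mapping of Recessive Lethals in Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classical forward-genetics mapping workflow for a recessive
    lethal mutation in Drosophila melanogaster: two-point meiotic
    recombination-frequency estimation from testcross counts with exact
    binomial confidence intervals, locus placement on the centiMorgan map by
    flank subtraction or least squares, cytogenetic deficiency/allele
    complementation interval solving on a polytene band lattice, tiling-PCR
    lesion localization with amplicon size arithmetic, densitometric
    target/control ratios, and Mendelian stage-survival statistics. A
    seedable synthetic-experiment generator emulates the three-generation
    mapping cross (repulsion-phase females, balancer-lethal classes, no male
    recombination), deficiency panels and tiling amplicon panels, so every
    analysis stage is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
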