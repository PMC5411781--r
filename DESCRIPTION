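Package: chromforge
Title: Reference-Assisted Chromosome Assembly, Scaffold Verification and
    Breakpoint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Upgrades fragmented genome assemblies to chromosome level using
    comparative evidence and read-pair physical coverage. Builds predicted
    chromosome fragments (PCFs) from syntenic fragments, identifies and
    verifies candidate chimeric joints, calibrates physical-coverage
    thresholds from verification outcomes, selects universally hybridizing
    probe panels, anchors PCFs to chromosomes with cytogenetic probe maps,
    detects and classifies evolutionary breakpoint regions (fusion, fission,
    intrachromosomal), and computes conserved-noncoding-element and
    transposable-element density statistics around breakpoints. A karyotype
    rearrangement simulator with complete ground truth makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
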