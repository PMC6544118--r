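Package: opstoich
Title: Operon Stoichiometry Analysis from Label-Free Proteome Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse protein stoichiometry within bacterial operons
    from label-free proteome quantification. Calibrates mass-spectrometry
    intensities to protein copies per cell against prior copy-number scales,
    quantifies within-operon expression variation with a coefficient-of-variation
    statistic tested against a permutation null, classifies operons as
    complex-coding or pathway-coding, relates stoichiometry to operon length,
    intergenic distances and translational coupling, and tests concordance
    between enzyme kinetics and protein abundance. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
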