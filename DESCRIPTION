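Package: pantx
Title: Pan-Transcriptome Presence/Absence Variation Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for expression presence/absence variation (ePAV)
    in diverse inbred panels: distribution-based ePAV calling from RPKM-style
    expression matrices, prediction of genomic presence/absence variants (PAV)
    from SNP-array missingness in gene windows, association of binary
    presence/absence markers with quantitative traits under principal-component
    structure correction, placement of novel (off-reference) sequences by
    composite linkage disequilibrium, pan-transcriptome size estimation by
    rarefaction with saturation-curve fitting, and the relation of parental
    PAV complementation to mid-parent heterosis in hybrids. Includes a
    synthetic-panel generator with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
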