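Package: vemap
Title: Variant Effect Mapping for PSAT1 Yeast Complementation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interpreting saturation variant-effect maps
    measured by yeast complementation, modelled on assays of human PSAT1 in a
    ser1 deletion background. Covers enumeration of SNV-accessible amino-acid
    substitutions and single-codon pool layout, variant calling from pooled
    amplicon codon counts with an empirical per-variant sequencing-error model,
    plate-image growth quantification (tiling, Otsu segmentation, pixelsum),
    linear-model growth normalization with plate, edge and neighbor effects,
    clinically anchored functional classification, a pairwise-additive model
    predicting biallelic (diploid) function from haploid allele scores, and
    statistics relating functional scores to evolutionary conservation. Seeded
    generators produce synthetic inputs with the statistical structure the
    analysis assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
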