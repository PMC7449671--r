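Package: twasim
Title: Simulation of Cross-Population Transcriptome Prediction and TWAS Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diverged and admixed populations from founder-mosaic
    haplotype panels, samples cis-eQTL architectures with a controllable
    proportion of eQTLs shared between ancestral populations, generates gene
    expression at a fixed cis-heritability, trains PrediXcan-style elastic-net
    expression prediction models with nested cross-validation, evaluates
    prediction portability across populations, and estimates the power of
    transcriptome-wide association tests across effect sizes, eQTL-sharing
    levels, and admixture proportions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    ggplot2
Config/testthat/edition: 3
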