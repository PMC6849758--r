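Package: climvuln
Title: Genomic Climate-Change Vulnerability Assessment for Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated climate-change vulnerability framework for
    population sets genotyped at thousands of SNPs: quality control of
    PED/MAP genotype data, Weir-Cockerham F_ST and AMOVA, FDist-style
    outlier scans against a simulated neutral envelope, latent-factor
    genotype-environment association with genomic-inflation correction
    and FDR control, circuit-theory landscape connectivity (effective
    resistance and cumulative current maps), multiple regression on
    distance matrices with permutation inference, and rule engines that
    combine exposure, sensitivity and range-shift potential into a
    per-population risk classification. Includes a seeded synthetic-data
    generator (Balding-Nichols genotypes with planted climate-adaptive
    loci plus paired current/future environmental rasters) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    jsonlite,
    knitr
Config/testthat/edition: 3
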