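Package: survfdr
Title: Local and Bayesian Survival False Discovery Rates for Genome-Wide
    Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Significance-threshold estimation for genome-wide association
    studies of quantitative traits. Implements Efron-style local false
    discovery rates with empirical-null maximum-likelihood fitting, and a
    Bayesian survival FDR in which allele classes are followed along a
    phenotype-ranked pseudo-time, per-SNP hazard factors feed a
    spike-and-slab prior, and significance is decided at a minor-allele
    frequency indexed posterior threshold. Includes SNP and phenotype
    quality control (bootstrap and Bayesian bootstrap checks, MAF, call
    rate, Hardy-Weinberg filters), a VanRaden genomic relationship matrix,
    a single-locus mixed-model scan, a structured-population genotype and
    phenotype simulator, and a one-command pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
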